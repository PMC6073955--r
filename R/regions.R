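#' Define a named set of residue regions
#'
#' A region set maps region names (e.g. `"c_tail"`, `"loop"`) to one or more
#' inclusive residue ranges on a chain, using the author numbering of the
#' input coordinates verbatim (1-based, inclusive on both ends; residues are
#' never renumbered).
#'
#' @param ... Named arguments, one per region. Each value is either a list of
#'   `list(chain =, start =, end =)` entries or a single such entry; `chain`
#'   is a one-character chain identifier.
#' @param .tbl Alternatively, a data frame with columns `region`, `chain`,
#'   `start`, `end` (overrides `...`).
#'
#' @return A tibble of class `region_set` with columns `region`, `chain`,
#'   `start`, `end`.
#'
#' @examples
#' region_set(
#'   loop   = list(chain = "A", start = 500, end = 514),
#'   c_tail = list(chain = "A", start = 553, end = 587)
#' )
#' @export
region_set <- function(..., .tbl = NULL) {
  if (is.null(.tbl)) {
    entries <- list(...)
    if (length(entries) == 0L) stop("region_set(): no regions supplied", call. = FALSE)
    if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
      stop("region_set(): every region must be named", call. = FALSE)
    }
    rows <- purrr::imap(entries, function(e, nm) {
      if (!is.null(e$chain)) e <- list(e)
      purrr::map(e, function(r) {
        tibble::tibble(
          region = nm,
          chain  = as.character(r$chain),
          start  = as.integer(r$start),
          end    = as.integer(r$end)
        )
      }) |> purrr::list_rbind()
    })
    tbl <- purrr::list_rbind(rows)
  } else {
    tbl <- tibble::as_tibble(.tbl)[, c("region", "chain", "start", "end")]
    tbl$start <- as.integer(tbl$start)
    tbl$end <- as.integer(tbl$end)
  }
  validate_region_set(tbl)
  class(tbl) <- c("region_set", class(tbl))
  tbl
}

validate_region_set <- function(tbl) {
  if (any(is.na(tbl$start)) || any(is.na(tbl$end))) {
    stop("region_set(): start/end must be integers", call. = FALSE)
  }
  if (any(tbl$start > tbl$end)) {
    bad <- tbl$region[tbl$start > tbl$end]
    stop("region_set(): start > end in region(s): ", paste(unique(bad), collapse = ", "),
      call. = FALSE)
  }
  if (any(tbl$start < 1L)) stop("region_set(): residue numbers must be >= 1", call. = FALSE)
  # ranges within one region entry may not overlap (per chain)
  split_tbl <- split(tbl, paste(tbl$region, tbl$chain))
  for (grp in split_tbl) {
    if (nrow(grp) > 1L) {
      o <- order(grp$start)
      s <- grp$start[o]; e <- grp$end[o]
      if (any(s[-1L] <= e[-length(e)])) {
        stop("region_set(): overlapping ranges within region '", grp$region[1L], "'",
          call. = FALSE)
      }
    }
  }
  invisible(tbl)
}

#' Read a region set from a YAML configuration file
#'
#' The expected layout mirrors
#' `regions: {c_tail: [{chain: A, start: 553, end: 587}], ...}`; a top-level
#' `regions:` key is optional.
#'
#' @param path Path to a YAML file.
#' @return A [region_set()] tibble.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("read_regions(): file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$regions)) cfg <- cfg$regions
  do.call(region_set, cfg)
}

#' Canonical ALAS2 analysis regions
#'
#' The region spans conventionally used for murine erythroid
#' 5-aminolevulinate synthase (ALAS2, mature numbering): N-terminal helix
#' 143-160, conserved catalytic core 161-552, active site loop 500-514,
#' beta13 strand 515-518, and the intrinsically disordered C-terminal tail
#' 553-587 (35 residues).
#'
#' @param chain Chain identifier(s); one region entry is emitted per chain.
#' @return A [region_set()] tibble.
#' @export
alas2_regions <- function(chain = "A") {
  spans <- list(
    n_helix   = c(143L, 160L),
    conserved = c(161L, 552L),
    loop      = c(500L, 514L),
    beta13    = c(515L, 518L),
    c_tail    = c(553L, 587L)
  )
  args <- purrr::imap(spans, function(sp, nm) {
    purrr::map(chain, function(ch) list(chain = ch, start = sp[1L], end = sp[2L]))
  })
  do.call(region_set, args)
}

#' Residues covered by a region
#'
#' @param regions A [region_set()].
#' @param region_name Region to expand.
#' @return Tibble with columns `chain`, `resno`, ordered by chain then
#'   residue number.
#' @export
region_residues <- function(regions, region_name) {
  rows <- regions[regions$region == region_name, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("region '", region_name, "' not found in region set", call. = FALSE)
  }
  out <- purrr::pmap(rows, function(region, chain, start, end) {
    tibble::tibble(chain = chain, resno = seq.int(start, end))
  }) |> purrr::list_rbind()
  dplyr::arrange(out, .data$chain, .data$resno)
}
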