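#' Canonical sleep stage vocabulary
#'
#' The five-class AASM scheme used throughout the package, in fixed order.
#' Stage codes are the zero-based positions in this order; the Test Cost
#' Index depends on this encoding, so it is fixed package-wide.
#'
#' @return Character vector `c("W", "S1", "S2", "S3", "REM")`.
#' @export
stages <- function() c("W", "S1", "S2", "S3", "REM")

#' Integer codes for the canonical stages
#'
#' @return Named integer vector mapping stage label to code, W = 0 ... REM = 4.
#' @export
stage_codes <- function() {
  stats::setNames(0:4, stages())
}

# Normalize a raw annotation token: case and separator insensitive.
normalize_label <- function(x) {
  gsub("[^A-Z0-9&]", "", toupper(trimws(x)))
}

#' Build a stage label map
#'
#' Maps raw hypnogram vocabulary onto the canonical five classes. The default
#' map covers R&K numeric codes (0 = W, 1-4 = S1..S4, 5 = REM; stage 4 merges
#' into S3 under AASM), the AASM "N" names, and common text spellings.
#' Matching is case-insensitive and ignores separators.
#'
#' @param extra Named character vector of additional raw -> canonical pairs
#'   (values must be canonical stage labels).
#' @param unknown Policy for labels outside the map: `"drop"` masks the epoch
#'   (it becomes `NA` in the hypnogram), `"error"` aborts.
#' @return An object of class `stage_map`.
#' @export
stage_map <- function(extra = NULL, unknown = c("drop", "error")) {
  unknown <- match.arg(unknown)
  map <- c(
    "0" = "W", "1" = "S1", "2" = "S2", "3" = "S3", "4" = "S3", "5" = "REM",
    W = "W", WK = "W", WAKE = "W", AWAKE = "W",
    N1 = "S1", S1 = "S1", STAGE1 = "S1",
    N2 = "S2", S2 = "S2", STAGE2 = "S2",
    N3 = "S3", S3 = "S3", STAGE3 = "S3",
    N4 = "S3", S4 = "S3", STAGE4 = "S3",
    R = "REM", REM = "REM", STAGER = "REM"
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      stop("`extra` must be a named character vector", call. = FALSE)
    }
    if (!all(extra %in% stages())) {
      stop("`extra` values must be canonical stage labels", call. = FALSE)
    }
    map[normalize_label(names(extra))] <- unname(extra)
  }
  structure(list(map = map, unknown = unknown), class = "stage_map")
}

#' Apply a stage map to raw labels
#'
#' Total over the declared vocabulary and idempotent on canonical labels.
#' Unknown labels become `NA` (drop policy) or raise an error (strict policy).
#'
#' @param x Character vector of raw stage labels.
#' @param sm A [stage_map()].
#' @return Character vector of canonical labels, possibly with `NA`.
#' @export
map_stages <- function(x, sm = stage_map()) {
  stopifnot(inherits(sm, "stage_map"))
  key <- normalize_label(as.character(x))
  out <- unname(sm$map[key])
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    if (sm$unknown == "error") {
      stop("unknown stage label(s): ", paste(unique(x[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  out
}
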