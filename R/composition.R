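# Cleavage-aligned residue composition: windows, frequency matrices and
# summary statistics of signal-peptide makeup.

window_positions <- function(up = 16, down = 10) c(-(up:1), 1:down)

#' Align cleavage-site windows
#'
#' For every call with a predicted signal peptide, extracts `up` residues
#' ending at the cleavage site and `down` residues after it, padding with
#' `-` on the left when the signal peptide is shorter than `up` and on the
#' right when the mature fragment is shorter than `down`.
#'
#' @param calls An `sp_calls` tibble (needs `sequence`, `sp_class`,
#'   `cleavage_after`); every call must have `sp_class != "NONE"` and at
#'   least one residue past the cleavage site.
#' @param up,down Window sizes on the signal-peptide and mature side.
#'   Defaults 16 and 10.
#' @return A tibble with `protein_id`, `sp_class` and `window` (a string of
#'   length `up + down`).
#' @export
align_cleavage_windows <- function(calls, up = 16, down = 10) {
  stopifnot(nrow(calls) > 0)
  if (any(calls$sp_class == "NONE")) {
    rlang::abort("cannot align a call without a signal peptide (class NONE)",
                 class = "secretr_error_input")
  }
  if (any(nchar(calls$sequence) <= calls$cleavage_after)) {
    bad <- calls$protein_id[nchar(calls$sequence) <= calls$cleavage_after][1]
    rlang::abort(paste0("no mature residue after cleavage for ", bad),
                 class = "secretr_error_input")
  }
  pad <- function(s, width, side) {
    fill <- strrep("-", width - nchar(s))
    if (side == "left") paste0(fill, s) else paste0(s, fill)
  }
  win <- purrr::map2_chr(calls$sequence, calls$cleavage_after, function(seq, cl) {
    sp_side <- substr(seq, max(1, cl - up + 1), cl)
    mat_side <- substr(seq, cl + 1, min(nchar(seq), cl + down))
    paste0(pad(sp_side, up, "left"), pad(mat_side, down, "right"))
  })
  tibble::tibble(
    protein_id = calls$protein_id,
    sp_class = calls$sp_class,
    window = win
  )
}

#' Position-specific residue frequency matrix
#'
#' Counts residues per aligned position (signal side -16..-1, mature side
#' +1..+10 for the default window) and normalises over the non-gap residues
#' of each position, as in a frequency-style sequence logo. Gap characters
#' never enter the denominator; an all-gap position has frequency `NA`.
#'
#' @param windows Output of [align_cleavage_windows()] (uniform window
#'   length).
#' @param up,down Window sizes used to build the windows.
#' @return A long tibble of class `sp_freq_matrix` with columns `position`,
#'   `residue`, `count`, `freq`, carrying the number of windows as
#'   attribute `n_windows`.
#' @export
frequency_matrix <- function(windows, up = 16, down = 10) {
  if (nrow(windows) == 0) {
    rlang::abort("no aligned windows supplied", class = "secretr_error_input")
  }
  width <- up + down
  if (any(nchar(windows$window) != width)) {
    rlang::abort("aligned windows must have uniform length",
                 class = "secretr_error_input")
  }
  pos <- window_positions(up, down)
  mat <- do.call(rbind, strsplit(windows$window, "", fixed = TRUE))
  residues <- sort(unique(c(AMINO_ACIDS, as.vector(mat[mat != "-"]))))
  grid <- tidyr::expand_grid(position = pos, residue = residues)
  counts <- purrr::map2_int(grid$position, grid$residue, function(p, r) {
    col <- mat[, which(pos == p)]
    sum(col == r)
  })
  totals <- vapply(seq_along(pos), function(j) sum(mat[, j] != "-"), integer(1))
  grid$count <- counts
  grid$freq <- ifelse(
    totals[match(grid$position, pos)] > 0,
    grid$count / totals[match(grid$position, pos)],
    NA_real_
  )
  out <- tibble::as_tibble(grid)
  attr(out, "n_windows") <- nrow(windows)
  class(out) <- c("sp_freq_matrix", class(out))
  out
}

#' Dominant residue at an aligned position
#'
#' The most frequent residue at a position, with its frequency and absolute
#' count. Ties are broken alphabetically and flagged.
#'
#' @param fm An [frequency_matrix()] result.
#' @param position Aligned position (negative = signal side, positive =
#'   mature side; there is no position 0).
#' @return A one-row tibble: `position`, `residue`, `freq`, `count`, `tie`.
#' @export
position_dominance <- function(fm, position) {
  col <- fm[fm$position == position, ]
  if (nrow(col) == 0) {
    rlang::abort("unknown position", class = "secretr_error_input")
  }
  if (all(is.na(col$freq)) || sum(col$count) == 0) {
    rlang::abort("position is all-gap", class = "secretr_error_input")
  }
  best <- max(col$count)
  hits <- sort(col$residue[col$count == best])
  tibble::tibble(
    position = position,
    residue = hits[1],
    freq = col$freq[col$residue == hits[1]],
    count = as.integer(best),
    tie = length(hits) > 1
  )
}

#' Basic-residue usage in n-regions
#'
#' Shares of lysine, arginine and histidine among the basic residues of the
#' n-regions of the supplied calls. Histidine is included here (it is a
#' basic residue in composition terms) even though the net-charge rule of
#' the classifier counts only K/R.
#'
#' @param calls An `sp_calls` tibble with region bounds (`n_end`).
#' @return A tibble with `residue`, `count` and `share` (shares sum to 1).
#' @export
basic_residue_usage <- function(calls) {
  use <- calls[!is.na(calls$n_end) & calls$n_end >= 1, ]
  if (nrow(use) == 0) {
    rlang::abort("no calls with an n-region", class = "secretr_error_input")
  }
  nreg <- substr(use$sequence, 1, use$n_end)
  res <- unlist(strsplit(nreg, "", fixed = TRUE))
  counts <- c(K = sum(res == "K"), R = sum(res == "R"), H = sum(res == "H"))
  if (sum(counts) == 0) {
    rlang::abort("no basic residues in any n-region", class = "secretr_error_input")
  }
  tibble::tibble(
    residue = names(counts),
    count = as.integer(counts),
    share = as.numeric(counts / sum(counts))
  )
}

#' Signal-peptide length summary per class
#'
#' Minimum, mean and maximum predicted signal-peptide length (the cleavage
#' position) per signal-peptide class.
#'
#' @param calls An `sp_calls` tibble.
#' @return A tibble with `sp_class`, `n`, `min_len`, `mean_len`, `max_len`.
#' @export
length_summary <- function(calls) {
  calls |>
    dplyr::filter(.data$sp_class != "NONE") |>
    dplyr::group_by(.data$sp_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      min_len = min(.data$cleavage_after),
      mean_len = mean(.data$cleavage_after),
      max_len = max(.data$cleavage_after),
      .groups = "drop"
    )
}

#' @method tidy sp_freq_matrix
#' @export
tidy.sp_freq_matrix <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sp_freq_matrix")
  tibble::as_tibble(out)
}
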