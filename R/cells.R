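#' @importFrom stats cor
NULL

#' Background intensity threshold
#'
#' Integer threshold below which a channel signal is considered background:
#' `floor(fraction * maxIntensity)`. On the 8-bit scale with the default 10%
#' fraction this is `floor(0.10 * 255) = 25`.
#'
#' @param maxIntensity maximum pixel intensity of the scale (default 255).
#' @param fraction background fraction of the maximum (default 0.10).
#' @return integer threshold.
#' @examples
#' backgroundThreshold() # 25
#' @export
backgroundThreshold <- function(maxIntensity = 255L, fraction = 0.10) {
  if (fraction < 0 || fraction > 1) stop("'fraction' must lie in [0, 1]")
  if (maxIntensity < 1) stop("'maxIntensity' must be >= 1")
  as.integer(floor(fraction * maxIntensity))
}

.checkCells <- function(cells) {
  need <- c("cell_id", "red", "green")
  if (!all(need %in% colnames(cells)))
    stop("cell table needs columns: ", paste(need, collapse = ", "))
  if (any(cells$red < 0 | cells$red > 255 | cells$green < 0 |
          cells$green > 255))
    stop("intensities must lie in [0, 255]")
  invisible(TRUE)
}

#' Classify cells by two-channel intensity ratio
#'
#' Cells with *both* channels below the background threshold are
#' `background` and excluded from ratio calculation. All other cells are
#' classified by the red/green ratio: `red` when ratio > 2, `green` when
#' ratio < 0.5, `yellow` (dual expression) when 0.5 <= ratio <= 2 (both
#' boundary ratios belong to yellow). A zero green channel with red signal
#' gives an infinite ratio (class `red`), and symmetrically a zero ratio
#' gives `green`; a non-background cell with both channels zero can only
#' arise with threshold 0 and is called `yellow` with ratio `NA`.
#'
#' @param cells data frame with columns `cell_id`, `red`, `green`
#'   (intensities on the 0-255 scale; red = first marker, green = second).
#' @param threshold background threshold, see [backgroundThreshold()].
#' @return the input data frame with added `ratio` and `klass` columns
#'   (`klass` one of `red`, `green`, `yellow`, `background`).
#' @examples
#' classifyCells(data.frame(cell_id = "c1", red = 100, green = 40))
#' @export
classifyCells <- function(cells, threshold = backgroundThreshold()) {
  cells <- as.data.frame(cells)
  .checkCells(cells)
  bg <- cells$red < threshold & cells$green < threshold
  ratio <- cells$red / cells$green            # Inf when green = 0, red > 0
  ratio[cells$red == 0 & cells$green == 0] <- NA_real_
  klass <- rep("yellow", nrow(cells))
  klass[!is.na(ratio) & ratio > 2] <- "red"
  klass[!is.na(ratio) & ratio < 0.5] <- "green"
  klass[bg] <- "background"
  ratio[bg] <- NA_real_
  cells$ratio <- ratio
  cells$klass <- klass
  cells
}

#' Co-expression summary of a cell population
#'
#' A cell is counted as co-expressing when both channels are at or above the
#' background threshold (i.e. both markers detectably expressed; this is
#' broader than the `yellow` ratio class, which additionally requires the
#' two signals to be within 2-fold of each other — both quantities are
#' reported). The Pearson correlation is computed over the intensity pairs of
#' non-background cells.
#'
#' @inheritParams classifyCells
#' @return a list with `fraction_coexpressing` (denominator: all input
#'   cells), `class_counts` (named integer vector over
#'   red/green/yellow/background, summing to the number of cells),
#'   `pearson_r`, `pearson_p` and `n_cells`.
#' @export
coexpressionSummary <- function(cells, threshold = backgroundThreshold()) {
  calls <- classifyCells(cells, threshold)
  counts <- table(factor(calls$klass,
                         levels = c("red", "green", "yellow", "background")))
  nb <- calls$klass != "background"
  if (sum(nb) < 3L)
    stop("need >= 3 non-background cells for the correlation")
  if (stats::sd(calls$red[nb]) == 0 || stats::sd(calls$green[nb]) == 0) {
    r <- NA_real_; pp <- NA_real_    # constant channel: correlation undefined
  } else {
    ct <- cor.test(calls$red[nb], calls$green[nb], method = "pearson")
    r <- unname(ct$estimate); pp <- ct$p.value
  }
  coexpr <- calls$red >= threshold & calls$green >= threshold
  list(fraction_coexpressing = mean(coexpr),
       class_counts = stats::setNames(as.integer(counts), names(counts)),
       pearson_r = r,
       pearson_p = pp,
       n_cells = nrow(calls))
}
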