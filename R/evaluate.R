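#' Dice similarity coefficient
#'
#' Computes `2 |A ∩ B| / (|A| + |B|)` between a predicted and a true
#' segmentation.  [LabelVolume-class] inputs are binarized by
#' `positiveLabels`; the default `{1, 2}` pools compact bone with the
#' filled marrow interior, i.e. evaluates the full bone region.  When
#' both masks are empty the coefficient is defined as 1 (perfect
#' agreement on absence) and a warning is raised.
#'
#' @param pred,truth aligned [BinaryMask-class] or [LabelVolume-class]
#'   objects.
#' @param positiveLabels integer labels counted as foreground when an
#'   input is a [LabelVolume-class].
#' @param caseId free-text identifier stored in the result.
#' @return a one-row `data.frame` with columns `case_id`, `dice`,
#'   `n_truth`, `n_pred`, `n_intersection`.
#' @examples
#' a <- BinaryMask(array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1)))
#' b <- BinaryMask(array(c(TRUE, FALSE, TRUE, FALSE), c(4, 1, 1)))
#' diceCoefficient(a, b)$dice  # 2*1/(2+2) = 0.5
#' @export
diceCoefficient <- function(pred, truth, positiveLabels = c(1L, 2L),
                            caseId = "case") {
    toMask <- function(x) {
        if (is(x, "LabelVolume")) x@voxels %in% positiveLabels
        else if (is(x, "BinaryMask")) x@voxels
        else stop("inputs must be BinaryMask or LabelVolume",
            call. = FALSE)
    }
    .checkAligned(pred, truth, "prediction and truth")
    p <- toMask(pred); t <- toMask(truth)
    np <- sum(p); nt <- sum(t); ni <- sum(p & t)
    dice <- if (np + nt == 0L) {
        warning("both masks are empty; Dice defined as 1",
            call. = FALSE)
        1
    } else 2 * ni / (np + nt)
    data.frame(case_id = caseId, dice = dice, n_truth = nt,
        n_pred = np, n_intersection = ni,
        stringsAsFactors = FALSE)
}

#' Summarize Dice results across cases
#'
#' Mean, minimum and maximum Dice over a set of cases, plus a frequency
#' histogram over `[0, 1]`.
#'
#' @param results a `data.frame` of rows from [diceCoefficient()] (or a
#'   list of such rows).
#' @param bins number of equal-width histogram bins over `[0, 1]`.
#' @return a list with `n`, `mean`, `min`, `max`, `breaks` and
#'   `counts` (`sum(counts) == n`).
#' @examples
#' r <- rbind(
#'   data.frame(case_id = "a", dice = 0.8, n_truth = 1, n_pred = 1,
#'     n_intersection = 1),
#'   data.frame(case_id = "b", dice = 1.0, n_truth = 1, n_pred = 1,
#'     n_intersection = 1))
#' summarizeDice(r)$mean
#' @export
summarizeDice <- function(results, bins = 10L) {
    if (is.list(results) && !is.data.frame(results))
        results <- do.call(rbind, results)
    if (is.null(results) || nrow(results) == 0L)
        stop("no Dice results to summarize", call. = FALSE)
    d <- results$dice
    stopifnot(is.numeric(d), all(d >= 0 & d <= 1))
    breaks <- seq(0, 1, length.out = bins + 1L)
    counts <- tabulate(pmin(pmax(findInterval(d, breaks,
        rightmost.closed = TRUE), 1L), bins), nbins = bins)
    list(n = length(d), mean = mean(d), min = min(d), max = max(d),
        breaks = breaks, counts = counts)
}
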