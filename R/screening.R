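#' Normalize a compound half-lifetime against the no-compound baseline
#'
#' The half-lifetime measured without any library compound serves as the
#' per-sample baseline; compound wells are expressed as the dimensionless
#' ratio `t_compound / t_baseline`, which removes sample-to-sample kinetic
#' differences before compounds are compared.
#'
#' @param t_compound Half-lifetime with the compound, minutes (> 0).
#' @param t_baseline Baseline half-lifetime of the same sample, minutes (> 0).
#' @return The dimensionless normalized ratio. Vectorized; `t_baseline` is
#'   recycled against `t_compound`.
#' @export
normalize_half_life <- function(t_compound, t_baseline) {
  if (any(!is.finite(t_baseline)) || any(t_baseline <= 0))
    stop("domain error: baseline half-life must be positive")
  if (any(!is.finite(t_compound)) || any(t_compound <= 0))
    stop("domain error: compound half-life must be positive")
  t_compound / t_baseline
}

#' Call flag compounds by the 3 x SD rule
#'
#' A compound is a "flag" when its normalized half-lifetime ratio deviates
#' from the across-compound center by more than three standard deviations.
#' The center is the mean of all compound ratios on the plate and the SD is
#' the sample (n-1) standard deviation across compounds; replicate variation
#' enters earlier, when replicate half-lives are averaged. A plate where all
#' ratios coincide has SD 0 and, consequently, no flags.
#'
#' @param ratios Named numeric vector of per-compound normalized ratios
#'   (names are compound ids); at least 2 compounds.
#' @return A data frame of class `flag_calls` with columns `compound_id`,
#'   `normalized_ratio`, `deviation` (ratio minus center), `flagged`, and
#'   `threshold` (the common 3 x SD value), plus attributes `center` and
#'   `sd`.
#' @export
call_flags <- function(ratios) {
  if (length(ratios) < 2L)
    stop("at least 2 compounds are required (SD is undefined for 1)")
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("normalized ratios must be positive and finite")
  ids <- names(ratios)
  if (is.null(ids)) ids <- sprintf("compound%02d", seq_along(ratios))
  center <- mean(ratios)
  s <- stats::sd(ratios)
  threshold <- 3 * s
  dev <- as.numeric(ratios - center)
  out <- data.frame(compound_id = ids,
                    normalized_ratio = as.numeric(ratios),
                    deviation = dev,
                    flagged = abs(dev) > threshold,
                    threshold = threshold)
  rownames(out) <- NULL
  attr(out, "center") <- center
  attr(out, "sd") <- s
  class(out) <- c("flag_calls", "data.frame")
  out
}

#' @export
print.flag_calls <- function(x, ...) {
  cat(sprintf("Flag calls over %d compounds: center %.4f, SD %.4f, threshold (3 x SD) %.4f\n",
              nrow(x), attr(x, "center"), attr(x, "sd"), x$threshold[[1L]]))
  flagged <- x$compound_id[x$flagged]
  if (length(flagged))
    cat("Flagged:", paste(flagged, collapse = ", "), "\n")
  else cat("No compound flagged\n")
  invisible(x)
}

#' Case/control ratio screen over a compound library
#'
#' For each compound, the mean normalized half-lifetime ratio over case (AD)
#' samples is divided by the mean over control (HC) samples. Compounds whose
#' score departs from 1 in either direction reshape the decay signal
#' differentially between the groups and are candidates for the diagnostic
#' panel.
#'
#' @param ad_ratios Named numeric vector: per-compound mean normalized ratio
#'   over case samples.
#' @param hc_ratios Same over control samples; must cover the same compound
#'   set and be strictly positive.
#' @return Named numeric vector of per-compound scores
#'   `ad_ratios / hc_ratios`, aligned on compound id.
#' @export
ad_hc_ratio_screen <- function(ad_ratios, hc_ratios) {
  if (is.null(names(ad_ratios)) || is.null(names(hc_ratios)))
    stop("ratio vectors must be named by compound id")
  if (!setequal(names(ad_ratios), names(hc_ratios)))
    stop("AD and HC ratio vectors must cover the same compound set")
  hc <- hc_ratios[names(ad_ratios)]
  bad <- names(hc)[!is.finite(hc) | hc <= 0]
  if (length(bad))
    stop("domain error: non-positive HC ratio for compound(s): ",
         paste(bad, collapse = ", "))
  ad_ratios / hc
}

#' Select the top-n screening panel
#'
#' Ranks compounds by `|log(score)|` in decreasing order, so a compound that
#' doubles the ratio and one that halves it are equally influential, and
#' returns the first `n`. Ties are broken by lexicographic compound id so the
#' ranking is deterministic.
#'
#' @param scores Named numeric vector of per-compound screen scores (> 0).
#' @param n Panel size, between 1 and the number of compounds.
#' @return An object of class `panel_selection`: list with `compounds`
#'   (ranked ids), `scores` (their scores, same order) and `n`.
#' @export
select_top_n <- function(scores, n) {
  if (length(n) != 1L || n < 1L) stop("n must be a positive integer")
  if (n > length(scores))
    stop("n (", n, ") exceeds the number of compounds (", length(scores), ")")
  if (is.null(names(scores))) stop("scores must be named by compound id")
  if (any(!is.finite(scores)) || any(scores <= 0))
    stop("scores must be positive and finite")
  stat <- abs(log(scores))
  o <- order(-stat, names(scores), method = "radix")
  sel <- o[seq_len(n)]
  structure(list(compounds = names(scores)[sel],
                 scores = as.numeric(scores[sel]),
                 n = as.integer(n)),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("Screening panel of", x$n, "compounds (ranked by |log score|):\n")
  print(data.frame(rank = seq_len(x$n), compound_id = x$compounds,
                   score = x$scores), row.names = FALSE)
  invisible(x)
}

# Replicate-averaged half-life per (sample, compound), converged fits only.
.mean_half_lives <- function(fits) {
  ok <- fits[fits$converged & is.finite(fits$half_life), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no converged fits available")
  agg <- stats::aggregate(half_life ~ sample_id + compound_id, data = ok,
                          FUN = mean)
  agg
}

#' Normalized compound ratios per sample from a plate fit table
#'
#' Averages replicate half-lives per (sample, compound), computes each
#' sample's baseline as the mean half-life of its [BASELINE_COMPOUND] wells,
#' and divides. Samples without a usable baseline well are dropped with a
#' warning.
#'
#' @param fits Fit table from [fit_plate()].
#' @return A data frame `sample_id`, `compound_id`, `ratio`.
#' @export
sample_compound_ratios <- function(fits) {
  agg <- .mean_half_lives(fits)
  base <- agg[agg$compound_id == BASELINE_COMPOUND, , drop = FALSE]
  if (nrow(base) == 0L)
    stop("no baseline (", BASELINE_COMPOUND, ") wells in the fit table")
  baseline <- stats::setNames(base$half_life, base$sample_id)
  cmp <- agg[agg$compound_id != BASELINE_COMPOUND, , drop = FALSE]
  no_base <- setdiff(unique(cmp$sample_id), names(baseline))
  if (length(no_base)) {
    warning("dropping sample(s) without a baseline well: ",
            paste(no_base, collapse = ", "))
    cmp <- cmp[!cmp$sample_id %in% no_base, , drop = FALSE]
  }
  cmp$ratio <- normalize_half_life(cmp$half_life, baseline[cmp$sample_id])
  cmp[, c("sample_id", "compound_id", "ratio")]
}

#' Run the library screen from fitted half-lives to a ranked panel
#'
#' End-to-end screening stage: replicate-averaged, baseline-normalized
#' ratios per sample; per-group per-compound means; case/control ratio
#' scores; 3 x SD flag calls on the scores; and the top-`panel_size` panel.
#'
#' @param fits Fit table from [fit_plate()].
#' @param metadata A `sample_metadata` table.
#' @param panel_size Number of panel compounds to rank (default 12).
#' @param case,control Group labels treated as case and control
#'   (defaults `"AD"`, `"HC"`).
#' @return A list of class `screen_result` with `scores` (named vector),
#'   `flags` (a `flag_calls` table over the scores), `panel`
#'   (a `panel_selection`), and `ratios` (per sample/compound).
#' @export
screen_compounds <- function(fits, metadata, panel_size = 12,
                             case = "AD", control = "HC") {
  ratios <- sample_compound_ratios(fits)
  grp <- stats::setNames(metadata$group, metadata$sample_id)
  unknown <- setdiff(unique(ratios$sample_id), names(grp))
  if (length(unknown))
    stop("sample(s) missing from metadata: ", paste(unknown, collapse = ", "))
  ratios$group <- grp[ratios$sample_id]
  per_group <- function(g) {
    sub <- ratios[ratios$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no samples in group '", g, "'")
    agg <- stats::aggregate(ratio ~ compound_id, data = sub, FUN = mean)
    stats::setNames(agg$ratio, agg$compound_id)
  }
  scores <- ad_hc_ratio_screen(per_group(case), per_group(control))
  structure(list(scores = scores,
                 flags = call_flags(scores),
                 panel = select_top_n(scores, panel_size),
                 ratios = ratios),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Compound library screen:", length(x$scores), "compounds\n")
  print(x$flags)
  print(x$panel)
  invisible(x)
}
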