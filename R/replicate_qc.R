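## Replicate outlier screening ----------------------------------------------
##
## A batch is an outlier when its VCD trend sits outside the replicate-mean
## +/- k*SD band, on one consistent side, for at least a set fraction of
## timepoints. The band is computed across all replicates of the condition,
## including the candidate.

#' Flag outlier batches by the VCD standard-deviation band rule
#'
#' For every condition with at least three replicates, computes the
#' per-timepoint mean and SD of VCD across the replicates and flags batches
#' lying strictly outside `mean +/- band_k * SD`, always on the same side,
#' at `frac_threshold` or more of the timepoints. With identical replicates
#' the band has zero width and nothing is flagged (strict inequality).
#' Conditions with fewer than three replicates are skipped with a warning
#' (the rule needs a majority).
#'
#' @param set a `culture_set`.
#' @param band_k band half-width in SD units (default 1).
#' @param frac_threshold minimum fraction of timepoints outside the band
#'   (default 0.5).
#' @return data.frame (class `outlier_report`): batch_id, condition_id,
#'   flagged, frac_outside, side, max_dev_sd.
#' @export
detect_outliers <- function(set, band_k = 1, frac_threshold = 0.5) {
  m <- set$measurements[set$measurements$variable == "VCD", ]
  out <- list()
  for (cid in unique(m$condition_id)) {
    mc <- m[m$condition_id == cid, ]
    batches <- sort(unique(mc$batch_id))
    days <- sort(unique(mc$day))
    V <- vapply(batches, function(b)
      mc$value[mc$batch_id == b][order(mc$day[mc$batch_id == b])],
      numeric(length(days)))
    if (length(batches) < 3) {
      warning("condition ", cid, ": fewer than 3 replicates; no outlier ",
              "screening applied")
      out[[cid]] <- data.frame(batch_id = batches, condition_id = cid,
                               flagged = FALSE, frac_outside = NA_real_,
                               side = NA_character_, max_dev_sd = NA_real_)
      next
    }
    mu <- rowMeans(V)
    sd_t <- apply(V, 1, stats::sd)
    dev <- sweep(V, 1, mu)
    z <- sweep(dev, 1, ifelse(sd_t > 0, sd_t, Inf), "/")
    rep_rows <- lapply(seq_along(batches), function(j) {
      above <- mean(z[, j] > band_k)
      below <- mean(z[, j] < -band_k)
      side <- if (above >= below) "+" else "-"
      frac <- max(above, below)
      data.frame(batch_id = batches[j], condition_id = cid,
                 flagged = frac >= frac_threshold,
                 frac_outside = frac, side = side,
                 max_dev_sd = max(abs(z[, j])))
    })
    out[[cid]] <- do.call(rbind, rep_rows)
  }
  rep <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(rep) <- c("outlier_report", class(rep))
  rep
}

#' Drop flagged batches from a culture set
#'
#' @param set a `culture_set`.
#' @param report an `outlier_report` from [detect_outliers()].
#' @return filtered `culture_set`.
#' @export
filter_outliers <- function(set, report) {
  bad <- report$batch_id[report$flagged]
  set$measurements <- set$measurements[!set$measurements$batch_id %in% bad, ]
  set$feed_events <- set$feed_events[!set$feed_events$batch_id %in% bad, ]
  set
}
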