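#' Default thresholds for copy-number classification
#'
#' Two presets are provided.  `"methylation"` (default) uses the +/-0.2
#' mean-segment-value thresholds applied to methylation-array copy-number
#' segmentations; `"wgs"` uses the +/-0.25 reporting rule of WGS paired
#' tumor-germline segmentation.  Both are inclusive.  `amplification` is
#' the log2 ratio at or above which a gene-level gain becomes an
#' amplification call (default 2.0, roughly > 8 copies on a diploid
#' background).
#'
#' @param preset `"methylation"` or `"wgs"`.
#' @param gain,loss,amplification numeric overrides of individual cutoffs.
#' @param focal_mode `"arm25"` (focal iff the segment covers <= 25% of its
#'   chromosome arm) or `"3mb"` (focal iff segment length <= 3 Mb).
#' @param focal_arm_fraction,focal_max_bp the two focal cutoffs.
#' @return list of thresholds used by [classify_segment()] and
#'   [call_gene_cnv()].
#' @export
cn_thresholds <- function(preset = c("methylation", "wgs"),
                          gain = NULL, loss = NULL, amplification = 2.0,
                          focal_mode = c("arm25", "3mb"),
                          focal_arm_fraction = 0.25, focal_max_bp = 3e6) {
  preset <- match.arg(preset)
  focal_mode <- match.arg(focal_mode)
  base <- if (preset == "methylation") 0.2 else 0.25
  list(gain = if (is.null(gain)) base else gain,
       loss = if (is.null(loss)) -base else loss,
       amplification = amplification,
       focal_mode = focal_mode,
       focal_arm_fraction = focal_arm_fraction,
       focal_max_bp = focal_max_bp)
}

#' Classify copy-number segments as gain/loss/neutral and focal/broad
#'
#' Direction is called from the mean log2 ratio with inclusive thresholds
#' (`seg_mean >= gain` is a gain, `<= loss` a loss, otherwise neutral).
#' Non-neutral segments are focal when they cover at most 25% of their
#' chromosome arm (mode `"arm25"`) or are at most 3 Mb long (mode `"3mb"`);
#' otherwise broad.  Neutral segments get extent `"not_applicable"`.
#' Segments spanning the centromere are split at the centromere first, so
#' the arm fraction is always well defined; both halves inherit the
#' seg_mean and therefore the direction.
#'
#' @param segments data frame of segments (`sample`, `chrom`, `start`,
#'   `end`, `seg_mean`; 0-based half-open), as from [read_seg()].
#' @param genome genome model (see [genome_model()]).
#' @param thresholds threshold list from [cn_thresholds()].
#' @return the input segments (centromere-split) with added columns `arm`,
#'   `arm_fraction`, `direction` and `extent`.
#' @examples
#' gm <- genome_model()
#' seg <- data.frame(sample = "S1", chrom = "chr4", start = 54e6,
#'                   end = 56e6, seg_mean = 0.5)
#' classify_segment(seg, gm)[, c("direction", "extent")]
#' @export
classify_segment <- function(segments, genome = genome_model(),
                             thresholds = cn_thresholds()) {
  if (!nrow(segments)) {
    out <- segments
    out$arm <- character(); out$arm_fraction <- numeric()
    out$direction <- character(); out$extent <- character()
    return(out)
  }
  segments$chrom <- normalize_chrom(segments$chrom)
  i <- match(segments$chrom, genome$chrom)
  if (anyNA(i)) {
    stop("segment on unknown chromosome: ",
         paste(unique(segments$chrom[is.na(i)]), collapse = ", "))
  }
  if (any(segments$start < 0 | segments$end > genome$length[i])) {
    stop("segment outside chromosome bounds")
  }
  if (any(segments$start >= segments$end)) stop("segment with start >= end")
  segments <- split_at_centromere(segments, genome)
  i <- match(segments$chrom, genome$chrom)
  cen <- genome$centromere[i]
  len <- genome$length[i]
  arm <- ifelse(segments$start < cen, "p", "q")
  arm_len <- ifelse(arm == "p", cen, len - cen)
  arm_fraction <- (segments$end - segments$start) / arm_len
  direction <- ifelse(segments$seg_mean >= thresholds$gain, "gain",
                      ifelse(segments$seg_mean <= thresholds$loss, "loss",
                             "neutral"))
  focal <- if (thresholds$focal_mode == "arm25") {
    arm_fraction <= thresholds$focal_arm_fraction
  } else {
    (segments$end - segments$start) <= thresholds$focal_max_bp
  }
  extent <- ifelse(direction == "neutral", "not_applicable",
                   ifelse(focal, "focal", "broad"))
  segments$arm <- arm
  segments$arm_fraction <- arm_fraction
  segments$direction <- direction
  segments$extent <- extent
  segments
}

split_at_centromere <- function(segments, genome) {
  i <- match(segments$chrom, genome$chrom)
  cen <- genome$centromere[i]
  spans <- segments$start < cen & segments$end > cen
  if (!any(spans)) return(segments)
  left <- segments[spans, ]; left$end <- cen[spans]
  right <- segments[spans, ]; right$start <- cen[spans]
  out <- rbind(segments[!spans, ], left, right)
  out[order(out$sample, out$chrom, out$start), , drop = FALSE]
}

#' Arm-level alteration frequencies across a cohort
#'
#' For each chromosome arm and direction (gain/loss), the fraction of
#' samples carrying at least one broad call of that direction on that arm.
#' Numerator and denominator are retained so printed frequencies such as
#' "10/25, 40.0%" can be reproduced verbatim.
#'
#' @param calls classified segments from [classify_segment()] for a whole
#'   cohort (multiple samples).
#' @param samples optional character vector giving the cohort denominator;
#'   defaults to the samples present in `calls`.
#' @return data frame with columns `chrom`, `arm`, `direction`,
#'   `n_altered`, `n_samples`, `frequency` (percent).
#' @export
arm_alteration_frequencies <- function(calls, samples = NULL) {
  if (is.null(samples)) samples <- unique(calls$sample)
  if (!length(samples)) stop("empty cohort")
  n <- length(samples)
  broad <- calls[calls$extent == "broad" & calls$direction != "neutral", ,
                 drop = FALSE]
  keys <- unique(calls[c("chrom", "arm")])
  keys <- keys[order(keys$chrom, keys$arm), , drop = FALSE]
  grid <- merge(keys, data.frame(direction = c("gain", "loss")))
  grid <- grid[order(grid$chrom, grid$arm, grid$direction), , drop = FALSE]
  grid$n_altered <- mapply(function(ch, am, dir) {
    length(unique(broad$sample[broad$chrom == ch & broad$arm == am &
                                 broad$direction == dir]))
  }, grid$chrom, grid$arm, grid$direction)
  grid$n_samples <- n
  grid$frequency <- 100 * grid$n_altered / n
  rownames(grid) <- NULL
  grid
}

#' Gene-level copy-number call
#'
#' The call for a gene in one sample comes from the overlapping segment
#' with maximal `|seg_mean|` (the deterministic stand-in for manual,
#' cross-platform adjudication): amplification when its seg_mean is at or
#' above the amplification threshold, gain when in `[gain, amplification)`,
#' loss at or below the loss threshold, otherwise neutral.  A gene with no
#' overlapping segment is neutral with a `no_coverage` flag.
#'
#' @param segments segments of one sample (or a cohort; calls are per
#'   sample x gene).
#' @param genes gene loci data frame (see [gene_loci()]).
#' @param thresholds threshold list from [cn_thresholds()].
#' @return data frame with columns `sample`, `symbol`, `call`, `seg_mean`,
#'   `no_coverage`.
#' @export
call_gene_cnv <- function(segments, genes = gene_loci(),
                          thresholds = cn_thresholds()) {
  segments$chrom <- normalize_chrom(segments$chrom)
  samples <- unique(segments$sample)
  out <- expand.grid(sample = samples, symbol = genes$symbol,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$call <- "neutral"
  out$seg_mean <- NA_real_
  out$no_coverage <- TRUE
  for (r in seq_len(nrow(out))) {
    g <- genes[genes$symbol == out$symbol[r], ]
    hit <- segments$sample == out$sample[r] & segments$chrom == g$chrom &
      segments$start < g$end & segments$end > g$start
    if (!any(hit)) next
    sm <- segments$seg_mean[hit]
    best <- sm[which.max(abs(sm))]
    out$seg_mean[r] <- best
    out$no_coverage[r] <- FALSE
    out$call[r] <- if (best >= thresholds$amplification) "amplification"
      else if (best >= thresholds$gain) "gain"
      else if (best <= thresholds$loss) "loss"
      else "neutral"
  }
  out
}

#' Count non-neutral copy-number calls per sample
#'
#' @param calls classified segments from [classify_segment()].
#' @return data frame with columns `sample`, `n_gain`, `n_loss`, `n_total`.
#' @export
cnv_count_per_sample <- function(calls) {
  samples <- unique(calls$sample)
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  out$n_gain <- vapply(samples, function(s)
    sum(calls$sample == s & calls$direction == "gain"), 0)
  out$n_loss <- vapply(samples, function(s)
    sum(calls$sample == s & calls$direction == "loss"), 0)
  out$n_total <- out$n_gain + out$n_loss
  rownames(out) <- NULL
  out
}
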