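#' Anchored conservation metaprofile
#'
#' Extracts per-base conservation scores in a window of +/- `flank` bases
#' around an anchor point of every interval and averages them per offset.
#' Anchors are strand-aware: the 5' end of a minus-strand interval is its
#' right edge, and offsets are oriented 5' to 3' (reversing the strand of
#' every interval reverses the profile). The midpoint of an even-length
#' interval is the left-of-center base. Windows extend across interval
#' boundaries into flanking sequence; offsets falling outside the scaffold or
#' onto missing track positions reduce the count at that offset but do not
#' bias the mean.
#'
#' @param intervals A [GenomicRanges::GRanges] (strand `*` is treated as
#'   `+`).
#' @param track A `"conservation_track"`.
#' @param anchor `"five_prime"`, `"midpoint"` or `"three_prime"`.
#' @param flank Window half-width in bases (default 150).
#' @return An object of class `"anchor_profile"`: `anchor`, `flank`,
#'   `offsets` (-flank..flank), `values` (mean score per offset), `counts`
#'   (contributing intervals per offset), `n_intervals`.
#' @export
anchor_profile <- function(intervals, track,
                           anchor = c("five_prime", "midpoint", "three_prime"),
                           flank = 150L) {
  anchor <- match.arg(anchor)
  if (length(intervals) == 0L) stop("empty interval set")
  stopifnot(inherits(track, "conservation_track"))
  sn <- as.character(GenomicRanges::seqnames(intervals))
  if (!all(sn %in% names(track$scores)))
    stop("interval(s) on scaffold absent from conservation track: ",
         paste(unique(setdiff(sn, names(track$scores))), collapse = ", "))
  str <- as.character(GenomicRanges::strand(intervals))
  str[str == "*"] <- "+"
  s <- GenomicRanges::start(intervals)
  e <- GenomicRanges::end(intervals)
  anchor_pos <- switch(anchor,
    five_prime = ifelse(str == "+", s, e),
    three_prime = ifelse(str == "+", e, s),
    midpoint = (s + e) %/% 2L)
  width <- 2L * flank + 1L
  sums <- numeric(width)
  counts <- integer(width)
  rel <- seq(-flank, flank)
  for (i in seq_along(intervals)) {
    v <- track$scores[[sn[i]]]
    pos <- anchor_pos[i] + (if (str[i] == "+") rel else -rel)
    ok <- pos >= 1L & pos <= length(v)
    vals <- rep(NA_real_, width)
    vals[ok] <- v[pos[ok]]
    have <- !is.na(vals)
    sums[have] <- sums[have] + vals[have]
    counts <- counts + have
  }
  structure(list(anchor = anchor, flank = as.integer(flank), offsets = rel,
                 values = ifelse(counts > 0L, sums / counts, NA_real_),
                 counts = counts, n_intervals = length(intervals)),
            class = "anchor_profile")
}

#' @export
print.anchor_profile <- function(x, ...) {
  cat("anchor_profile [", x$anchor, "]: +/-", x$flank, " bp over ",
      x$n_intervals, " interval(s), mean score ",
      sprintf("%.4f", mean(x$values, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Exon-intron boundary conservation contrast
#'
#' For a profile anchored at an intron end the window straddles the
#' exon-intron boundary: at the 5' end of the intron the exon lies on the
#' upstream (negative-offset) side, at the 3' end on the downstream side.
#' Returns the mean score over exon-side offsets minus the mean over
#' intron-side offsets (offset 0, the boundary base, is excluded from both).
#'
#' @param profile An `"anchor_profile"` computed at intron 5' or 3' anchors.
#' @param exon_side `"upstream"` (intron 5' anchors) or `"downstream"`
#'   (intron 3' anchors).
#' @return Mean exon-side score minus mean intron-side score.
#' @export
boundary_contrast <- function(profile, exon_side = c("upstream", "downstream")) {
  exon_side <- match.arg(exon_side)
  stopifnot(inherits(profile, "anchor_profile"))
  up <- profile$offsets < 0L
  down <- profile$offsets > 0L
  exon <- if (exon_side == "upstream") up else down
  intron <- if (exon_side == "upstream") down else up
  mean(profile$values[exon], na.rm = TRUE) -
    mean(profile$values[intron], na.rm = TRUE)
}

#' Tidy an anchor profile
#'
#' @param profile An `"anchor_profile"`.
#' @return A data.frame with columns `offset`, `mean_score`, `n`.
#' @export
anchor_profile_table <- function(profile) {
  data.frame(offset = profile$offsets, mean_score = profile$values,
             n = profile$counts)
}
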