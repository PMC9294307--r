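#' Zero-substitution rule for subthreshold peaks
#'
#' Peaks whose omnibus-corrected pseudo-Z is not significant represent the
#' absence of a reliable cortical response; their value is set to exactly
#' zero before the normalized hemispheric indices are computed. Substitution
#' events are reported via a message so they can be audited.
#'
#' @param peak An `roi_peak` from [extract_roi_peak()], or a numeric vector
#'   of corrected pseudo-Z values paired with a logical `significant` vector.
#' @param significant Logical vector (only when `peak` is numeric).
#' @param quiet Suppress the substitution message.
#' @return Numeric pseudo-Z value(s) for index computation.
#' @export
apply_subthreshold_rule <- function(peak, significant = NULL, quiet = FALSE) {
  if (inherits(peak, "roi_peak")) {
    value <- peak$pz_corrected
    significant <- peak$significant
  } else {
    value <- peak
    if (is.null(significant))
      stop("significant flags required for numeric input")
  }
  out <- ifelse(significant, value, 0)
  nsub <- sum(!significant)
  if (nsub > 0 && !quiet)
    message(nsub, " subthreshold peak(s) set to zero")
  out
}

# shared normalized-difference core of Eqs (1) and (2); NA when both inputs
# are zero (0/0 is undefined, not symmetric)
.normalized_difference <- function(a, b) {
  if (any(c(a, b) < 0, na.rm = TRUE))
    stop("inputs must be >= 0 (apply the subthreshold rule first)")
  s <- a + b
  ifelse(is.na(s) | s == 0, NA_real_, (a - b) / s * 100)
}

#' Cortical lateralization (%)
#'
#' Normalized right-minus-left auditory-cortex activation difference for one
#' stimulation condition:
#' `(right_ac - left_ac) / (right_ac + left_ac) * 100`.
#' Positive values indicate right-hemispheric, negative values
#' left-hemispheric lateralization. Both inputs are omnibus-corrected,
#' zero-substituted peak pseudo-Z values; a 0/0 case returns `NA`.
#'
#' @param right_ac,left_ac Peak pseudo-Z per hemisphere (vectors allowed).
#' @return Lateralization in percent, in `[-100, 100]` or `NA`.
#' @export
cortical_lateralization <- function(right_ac, left_ac) {
  .normalized_difference(right_ac, left_ac)
}

#' Cortical representation of input (%)
#'
#' Normalized right-ear minus left-ear response difference within one
#' hemisphere: `(right_ear - left_ear) / (right_ear + left_ear) * 100`.
#' Positive values indicate stronger representation of the right (first
#' implanted) ear, negative values of the left (second implanted) ear. Not
#' defined for bilateral stimulation.
#'
#' @param right_ear,left_ear Peak pseudo-Z evoked by each ear in the same
#'   hemisphere (zero-substituted).
#' @param condition Optional condition label; passing `"bilateral"` is a
#'   usage error.
#' @return Representation in percent, in `[-100, 100]` or `NA`.
#' @export
cortical_representation <- function(right_ear, left_ear, condition = NULL) {
  if (!is.null(condition) && any(condition == "bilateral"))
    stop("usage error: cortical representation is not defined for bilateral stimulation")
  .normalized_difference(right_ear, left_ear)
}

#' Bilateral enhancement (pseudo-Z difference)
#'
#' Bilateral-minus-unilateral response difference in the ipsilateral
#' hemisphere: for the left auditory cortex the left-ear unilateral response
#' is subtracted, for the right the right-ear response. Positive values are
#' the typical ipsilateral enhancement under bilateral stimulation; negative
#' values mark its absence.
#'
#' @param bilateral Peak pseudo-Z under bilateral stimulation.
#' @param ipsilateral_unilateral Peak pseudo-Z for unilateral stimulation of
#'   the ear on the same side as `hemisphere`.
#' @param hemisphere `"left"` or `"right"`.
#' @param ear Optional ear label of the unilateral response; must match
#'   `hemisphere` (left AC pairs with left ear, right with right).
#' @return Signed pseudo-Z difference.
#' @export
bilateral_enhancement <- function(bilateral, ipsilateral_unilateral,
                                  hemisphere = c("left", "right"),
                                  ear = NULL) {
  hemisphere <- match.arg(hemisphere)
  if (!is.null(ear) && any(ear != hemisphere))
    stop("usage error: ", hemisphere,
         " auditory cortex enhancement uses the ", hemisphere,
         "-ear unilateral response")
  bilateral - ipsilateral_unilateral
}

#' Bilateral speech-perception benefit, raw and normalized
#'
#' The benefit an ear provides in bilateral listening compared to listening
#' with the opposite ear alone. Raw benefit is
#' `bilateral_score - opposite_ear_score` (percentage points); normalized
#' benefit expresses it as a percentage of the attainable headroom:
#' `(bilateral - opposite) / (100 - opposite) * 100`. When the opposite ear
#' already scores 100% no headroom exists and the normalized benefit is `NA`.
#'
#' @param bilateral_score Percent words correct, bilateral condition.
#' @param opposite_ear_score Percent words correct for the opposite ear
#'   alone.
#' @return A `data.frame` with columns `benefit` and `normalized_benefit`.
#' @export
normalized_bilateral_benefit <- function(bilateral_score, opposite_ear_score) {
  if (any(c(bilateral_score, opposite_ear_score) < 0 |
            c(bilateral_score, opposite_ear_score) > 100, na.rm = TRUE))
    stop("scores must lie in [0, 100]")
  raw <- bilateral_score - opposite_ear_score
  norm <- ifelse(opposite_ear_score == 100, NA_real_,
                 raw / (100 - opposite_ear_score) * 100)
  data.frame(benefit = raw, normalized_benefit = norm)
}

#' Assemble the tidy index table from ROI peak records
#'
#' Takes a long peak table (one row per participant x session x condition x
#' hemisphere) and computes, per participant and session: zero-substituted
#' peak pseudo-Z, cortical lateralization per condition, cortical
#' representation per hemisphere, and bilateral enhancement per hemisphere.
#'
#' @param peaks A `data.frame` with columns `participant_id`, `session`,
#'   `time_bin`, `condition` (`CI1_right`, `CI2_left`, `bilateral`),
#'   `hemisphere` (`left`, `right`), `pz_corrected`, `significant`.
#' @return A list with `wide` (one row per participant x session) and `long`
#'   (one row per participant x session x measure) data frames. Substitution
#'   counts are attached as attribute `"n_substituted"`.
#' @export
build_index_table <- function(peaks) {
  need <- c("participant_id", "session", "time_bin", "condition",
            "hemisphere", "pz_corrected", "significant")
  stopifnot(all(need %in% names(peaks)))
  peaks$pz_used <- apply_subthreshold_rule(peaks$pz_corrected,
                                           peaks$significant, quiet = TRUE)
  n_sub <- sum(!peaks$significant)

  key <- unique(peaks[c("participant_id", "session", "time_bin")])
  get_pz <- function(p, s, cond, hemi) {
    v <- peaks$pz_used[peaks$participant_id == p & peaks$session == s &
                         peaks$condition == cond & peaks$hemisphere == hemi]
    if (length(v) != 1L) NA_real_ else v
  }
  rows <- lapply(seq_len(nrow(key)), function(i) {
    p <- key$participant_id[i]; s <- key$session[i]
    pz <- sapply(c(CI1_right = "CI1_right", CI2_left = "CI2_left",
                   bilateral = "bilateral"), function(cond)
                     c(left = get_pz(p, s, cond, "left"),
                       right = get_pz(p, s, cond, "right")))
    data.frame(
      participant_id = p, session = s, time_bin = key$time_bin[i],
      pz_ci1_left = pz["left", "CI1_right"],
      pz_ci1_right = pz["right", "CI1_right"],
      pz_ci2_left = pz["left", "CI2_left"],
      pz_ci2_right = pz["right", "CI2_left"],
      pz_bil_left = pz["left", "bilateral"],
      pz_bil_right = pz["right", "bilateral"],
      lateralization_ci1 = cortical_lateralization(pz["right", "CI1_right"],
                                                   pz["left", "CI1_right"]),
      lateralization_ci2 = cortical_lateralization(pz["right", "CI2_left"],
                                                   pz["left", "CI2_left"]),
      lateralization_bil = cortical_lateralization(pz["right", "bilateral"],
                                                   pz["left", "bilateral"]),
      representation_left = cortical_representation(pz["left", "CI1_right"],
                                                    pz["left", "CI2_left"]),
      representation_right = cortical_representation(pz["right", "CI1_right"],
                                                     pz["right", "CI2_left"]),
      enhancement_left = bilateral_enhancement(pz["left", "bilateral"],
                                               pz["left", "CI2_left"],
                                               "left"),
      enhancement_right = bilateral_enhancement(pz["right", "bilateral"],
                                                pz["right", "CI1_right"],
                                                "right"),
      stringsAsFactors = FALSE)
  })
  wide <- do.call(rbind, rows)
  rownames(wide) <- NULL

  measures <- setdiff(names(wide), c("participant_id", "session", "time_bin"))
  long <- do.call(rbind, lapply(measures, function(m) {
    data.frame(participant_id = wide$participant_id, session = wide$session,
               time_bin = wide$time_bin, measure = m, value = wide[[m]],
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  out <- list(wide = wide, long = long)
  attr(out, "n_substituted") <- n_sub
  out
}
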