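#' Check scan records against the DCE protocol
#'
#' Flags, per scan record, the four protocol-violation types observed in
#' multi-center DCE studies: frame interval deviating from the protocol's
#' beyond `interval_tol`, fewer frames than prescribed, failure to inject
#' contrast, and an imaging slab not centered on the carotid bifurcation.
#' A subject is protocol-compliant only if every scan passes all four
#' checks.
#'
#' @param roster A scan-level roster data.frame (see [generate_roster()])
#'   with columns `subject_id`, `scan`, `frame_interval_actual`,
#'   `n_frames_actual`, `contrast_injected`,
#'   `slab_centered_on_bifurcation`.
#' @param protocol An [acq_protocol()] giving the nominal interval and
#'   frame count.
#' @param interval_tol Allowed absolute deviation of the frame interval, s.
#'
#' @return A list with `scans` (the roster plus logical flag columns
#'   `bad_interval`, `too_few_frames`, `no_contrast`, `misaligned`,
#'   `violation`) and `subjects` (per-subject data.frame with `compliant`
#'   and the dominant `reason`).
#' @export
check_protocol <- function(roster, protocol, interval_tol = 1) {
  req <- c("subject_id", "scan", "frame_interval_actual", "n_frames_actual",
           "contrast_injected", "slab_centered_on_bifurcation")
  miss <- setdiff(req, names(roster))
  if (length(miss)) stop("roster missing column(s): ", paste(miss, collapse = ", "))
  validate_protocol(protocol)

  scans <- roster
  scans$bad_interval <- abs(scans$frame_interval_actual - protocol$frame_interval) > interval_tol
  scans$too_few_frames <- scans$n_frames_actual < protocol$n_frames
  scans$no_contrast <- !scans$contrast_injected
  scans$misaligned <- !scans$slab_centered_on_bifurcation
  scans$violation <- scans$bad_interval | scans$too_few_frames |
    scans$no_contrast | scans$misaligned

  ids <- unique(scans$subject_id)
  reason_of <- function(s) {
    if (any(s$bad_interval)) return("incorrect time interval")
    if (any(s$too_few_frames)) return("too few time frames")
    if (any(s$no_contrast)) return("failure to inject contrast agent")
    if (any(s$misaligned)) return("improper alignment of images")
    "none"
  }
  subj <- do.call(rbind, lapply(ids, function(id) {
    s <- scans[scans$subject_id == id, , drop = FALSE]
    data.frame(subject_id = id,
               compliant = !any(s$violation),
               reason = reason_of(s),
               stringsAsFactors = FALSE)
  }))
  list(scans = scans, subjects = subj)
}

#' Apply the study exclusion cascade to a roster
#'
#' Reproduces the two-stage exclusion of a multi-center reproducibility
#' study: subjects with any significant protocol violation in at least one
#' scan are removed first; among the compliant, subjects with
#' uninterpretable image quality (score 1) in at least one scan are
#' removed next; the remainder are analyzed. Enrolled =
#' protocol-excluded + quality-excluded + analyzed, always.
#'
#' @inheritParams check_protocol
#' @return A list with counts (`enrolled`, `protocol_excluded`,
#'   `quality_excluded`, `analyzed`), the per-subject `subjects` table
#'   (with `status` in excluded_protocol/excluded_quality/analyzed and
#'   `vendor` when present), and `analyzed_ids`.
#' @export
exclusion_cascade <- function(roster, protocol = acq_protocol("GE"),
                              interval_tol = 1) {
  chk <- check_protocol(roster, protocol, interval_tol)
  subj <- chk$subjects
  quality_bad <- tapply(roster$quality_score == 1L, roster$subject_id, any)
  subj$quality_bad <- as.logical(quality_bad[subj$subject_id])
  subj$status <- ifelse(!subj$compliant, "excluded_protocol",
                        ifelse(subj$quality_bad, "excluded_quality", "analyzed"))
  if ("vendor" %in% names(roster)) {
    vend <- tapply(roster$vendor, roster$subject_id, function(v) v[1])
    subj$vendor <- as.character(vend[subj$subject_id])
  }
  counts <- c(
    enrolled = nrow(subj),
    protocol_excluded = sum(subj$status == "excluded_protocol"),
    quality_excluded = sum(subj$status == "excluded_quality"),
    analyzed = sum(subj$status == "analyzed")
  )
  list(counts = counts, subjects = subj,
       analyzed_ids = subj$subject_id[subj$status == "analyzed"])
}
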