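#' Synthetic multi-center study roster with protocol and quality flags
#'
#' Generates the scan-level roster of a 51-subject, 15-site scan-rescan
#' study with the exclusion structure of a multi-center DCE trial: exactly
#' 10 subjects carry a significant protocol violation in at least one scan
#' (3 incorrect frame interval, 2 too few time frames, 2 contrast-injection
#' failure, 3 improper slab alignment; categories disjoint, spread across 9
#' sites with one two-subject site fully excluded), and 6 of the remaining
#' 41 subjects carry uninterpretable image quality (score 1) in at least
#' one scan, spread across 6 sites. The 35 clean subjects split 20 GE / 15
#' Philips. The seed controls which subject within a site carries each
#' flag, which scan is affected, and the nuisance values (wrong intervals,
#' frame counts, quality scores 2-4).
#'
#' @param seed Integer seed.
#' @return A data.frame with 102 rows (51 subjects x 2 scans) and columns
#'   `subject_id`, `site`, `vendor`, `scan`, `frame_interval_actual` (s),
#'   `n_frames_actual`, `contrast_injected`, `slab_centered_on_bifurcation`,
#'   `quality_score` (1 = uninterpretable, 4 = excellent).
#' @export
#' @examples
#' r <- generate_roster(seed = 1)
#' nrow(r)  # 102
generate_roster <- function(seed = 1L) {
  site_sizes <- c(6L, 5L, 4L, 4L, 3L, 3L, 2L, 2L,   # GE sites 1-8
                  5L, 4L, 4L, 3L, 2L, 2L, 2L)       # Philips sites 9-15
  site_vendor <- rep(c("GE", "Philips"), times = c(8L, 7L))
  n_subj <- sum(site_sizes)  # 51

  subj_site <- rep(seq_along(site_sizes), times = site_sizes)
  subj_vendor <- site_vendor[subj_site]
  subj_id <- sprintf("S%02d", seq_len(n_subj))

  with_seed(seed, {
    # Protocol violators: both subjects of site 8, plus one subject from
    # each of sites 1-4 (GE) and 9-12 (Philips) -> 10 subjects, 9 sites.
    pick_one <- function(site) {
      ids <- which(subj_site == site)
      ids[sample.int(length(ids), 1L)]
    }
    protocol_idx <- c(which(subj_site == 8L),
                      vapply(c(1:4, 9:12), pick_one, integer(1)))
    # Disjoint violation categories permuted over the 10 violators.
    categories <- sample(rep(c("interval", "frames", "contrast", "alignment"),
                             times = c(3L, 2L, 2L, 3L)))
    # Quality exclusions: one subject from each of sites 5-7 and 13-15,
    # none of which holds a protocol violator.
    quality_idx <- vapply(c(5:7, 13:15), pick_one, integer(1))

    n_scan <- 2L * n_subj
    roster <- data.frame(
      subject_id = rep(subj_id, each = 2L),
      site = rep(subj_site, each = 2L),
      vendor = rep(subj_vendor, each = 2L),
      scan = rep(1:2, times = n_subj),
      frame_interval_actual = rep(18, n_scan),
      n_frames_actual = rep(18L, n_scan),
      contrast_injected = rep(TRUE, n_scan),
      slab_centered_on_bifurcation = rep(TRUE, n_scan),
      quality_score = sample(2:4, n_scan, replace = TRUE,
                             prob = c(0.25, 0.45, 0.30)),
      stringsAsFactors = FALSE
    )

    row_of <- function(subj, scan) (subj - 1L) * 2L + scan
    for (k in seq_along(protocol_idx)) {
      subj <- protocol_idx[k]
      scans <- if (stats::runif(1) < 0.25) 1:2 else sample(1:2, 1L)
      rows <- row_of(subj, scans)
      switch(categories[k],
        interval = {
          roster$frame_interval_actual[rows] <- sample(c(12, 15, 20, 24), 1L)
        },
        frames = {
          roster$n_frames_actual[rows] <- sample(10:15, 1L)
        },
        contrast = {
          roster$contrast_injected[rows] <- FALSE
        },
        alignment = {
          roster$slab_centered_on_bifurcation[rows] <- FALSE
        })
    }
    for (subj in quality_idx) {
      scans <- if (stats::runif(1) < 0.2) 1:2 else sample(1:2, 1L)
      roster$quality_score[row_of(subj, scans)] <- 1L
    }
    roster
  })
}
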