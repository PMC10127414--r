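# Group-level reference summaries (means / SDs, proportions, counts) used as
# defaults by the synthetic cohort generator.  All volumes are mm^3; TIV,
# navigation errors and cognitive composites are on standardized scales.

scn_groups <- c("NC", "G-SCD", "B-SCD", "MCI")

# Default group sizes of the four diagnostic groups
scn_group_sizes <- c("NC" = 77L, "G-SCD" = 40L, "B-SCD" = 40L, "MCI" = 23L)

# ROI volume reference: one row per ROI, columns interleave mean/SD for
# NC, G-SCD, B-SCD, MCI.
.roi_reference_raw <- matrix(c(
  # 15 subcortical nuclei
  535.24,  40.62,  539.47,  51.05,  515.08,  42.47,  499.95,  36.37, # Basal forebrain
  5946.67, 563.92, 5955.59, 650.65, 5801.25, 580.15, 5567.23, 414.48, # L-Thalamus
  3077.73, 354.22, 3176.93, 371.77, 3065.99, 417.08, 3084.21, 403.91, # L-Caudate
  4519.79, 448.30, 4493.13, 518.10, 4440.52, 554.15, 4398.10, 347.17, # L-Putamen
  1862.60, 240.92, 1847.12, 219.02, 1807.77, 254.06, 1781.75, 262.65, # L-Pallidum
  3577.23, 352.48, 3576.78, 424.65, 3484.67, 345.05, 3312.63, 293.79, # L-Hippocampus
  1359.26, 221.99, 1281.10, 230.21, 1301.93, 220.96, 1232.48, 210.16, # L-Amygdala
  502.48,  87.68,  493.19,  82.03,  487.24,  77.49,  448.04,  91.01, # L-Accumbens
  5813.13, 576.93, 5757.73, 576.39, 5667.74, 572.91, 5498.96, 420.97, # R-Thalamus
  3176.42, 349.43, 3277.09, 376.46, 3171.37, 415.60, 3226.93, 493.72, # R-Caudate
  4503.70, 501.74, 4494.81, 492.07, 4466.18, 546.24, 4406.74, 401.24, # R-Putamen
  1757.02, 198.94, 1784.53, 213.82, 1754.38, 250.43, 1702.58, 246.80, # R-Pallidum
  3678.94, 379.55, 3677.84, 450.97, 3575.85, 407.17, 3319.50, 345.14, # R-Hippocampus
  1534.93, 278.04, 1484.69, 256.68, 1474.44, 231.41, 1358.29, 171.53, # R-Amygdala
  494.64,  81.59,  489.63,  83.88,  475.37,  66.99,  454.74,  78.25, # R-Accumbens
  # 5 basal forebrain subfields
  85.80,   8.03,   86.40,   9.27,   81.96,   6.34,   79.78,   5.74,  # Ch4p
  142.37,  10.17,  144.01,  13.01,  137.13,  11.32,  134.19,  10.03, # Ch4a-i
  135.73,  10.25,  136.77,  13.27,  130.98,  11.29,  126.73,  9.47,  # Ch3
  104.60,  8.16,   104.93,  10.01,  101.44,  9.79,   98.22,   7.23,  # NSP
  66.74,   6.73,   67.36,   8.00,   63.56,   6.17,   61.03,   6.91,  # Ch1/2
  # 12 right hippocampal subfields
  533.30,  68.27,  541.56,  73.41,  521.76,  77.54,  494.31,  68.98, # Tail
  405.03,  48.60,  407.07,  50.87,  398.36,  47.67,  368.83,  47.03, # Subiculum
  599.83,  77.12,  590.84,  78.50,  571.73,  69.33,  539.58,  59.69, # CA1
  174.85,  34.63,  168.29,  29.36,  164.64,  30.02,  154.86,  24.73, # Fissure
  281.58,  29.56,  278.40,  33.66,  278.86,  30.81,  256.79,  38.83, # Presubiculum
  52.84,   9.26,   51.21,   8.47,   52.46,   9.98,   49.38,   7.39,  # Parasubiculum
  528.53,  58.90,  525.75,  62.01,  512.38,  53.09,  474.96,  54.67, # Molecular layer
  270.86,  34.67,  264.55,  30.37,  260.47,  27.93,  242.87,  28.10, # Dentate gyrus
  185.85,  30.40,  186.76,  28.44,  179.64,  25.24,  166.14,  25.92, # CA2/3
  229.72,  29.34,  224.50,  25.27,  222.68,  24.02,  207.10,  22.62, # CA4
  72.61,   17.86,  64.33,   13.40,  65.69,   15.80,  64.57,   18.49, # Fimbria
  55.43,   8.44,   54.19,   9.15,   53.15,   9.60,   48.61,   8.14   # HATA
), ncol = 8, byrow = TRUE)

scn_subcortical_nuclei <- c(
  "Basal forebrain", "L-Thalamus", "L-Caudate", "L-Putamen", "L-Pallidum",
  "L-Hippocampus", "L-Amygdala", "L-Accumbens", "R-Thalamus", "R-Caudate",
  "R-Putamen", "R-Pallidum", "R-Hippocampus", "R-Amygdala", "R-Accumbens")
scn_bf_subfields <- c("Ch4p", "Ch4a-i", "Ch3", "NSP", "Ch1/2")
scn_hc_subfields <- c(
  "Tail", "Subiculum", "CA1", "Fissure", "Presubiculum", "Parasubiculum",
  "Molecular layer", "Dentate gyrus", "CA2/3", "CA4", "Fimbria", "HATA")
scn_all_rois <- c(scn_subcortical_nuclei, scn_bf_subfields, scn_hc_subfields)

# group x ROI matrices of means and SDs
scn_roi_means <- t(.roi_reference_raw[, c(1, 3, 5, 7)])
scn_roi_sds <- t(.roi_reference_raw[, c(2, 4, 6, 8)])
dimnames(scn_roi_means) <- list(scn_groups, scn_all_rois)
dimnames(scn_roi_sds) <- list(scn_groups, scn_all_rois)

.ms <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE,
              dimnames = list(scn_groups, c("mean", "sd")))
  m
}

# demographic / clinical reference (per-group mean, SD)
scn_covariate_reference <- list(
  age = .ms(65.36, 5.80, 64.40, 5.49, 65.18, 5.90, 65.87, 5.80),
  education = .ms(12.86, 2.97, 12.68, 2.64, 11.79, 2.36, 12.65, 3.61),
  tiv = .ms(0.05, 0.99, 0.11, 0.90, -0.09, 1.07, -0.21, 1.10),
  sex_male = c("NC" = 14 / 77, "G-SCD" = 7 / 40, "B-SCD" = 7 / 40, "MCI" = 4 / 23),
  scanner_tx = c("NC" = 30 / 77, "G-SCD" = 13 / 40, "B-SCD" = 17 / 40, "MCI" = 9 / 23),
  scdq = .ms(3.90, 1.99, 5.68, 1.29, 5.81, 1.25, 5.20, 2.07),
  mmse = .ms(28.73, 1.19, 28.75, 1.28, 28.43, 1.53, 27.26, 3.55))

# standardized distance error of the navigation task (lower = better);
# trial_sd is the within-subject trial-to-trial noise around the subject's
# latent error level
scn_navigation_reference <- list(
  error = .ms(-0.28, 0.65, -0.51, 0.27, 0.80, 0.69, 0.42, 1.03),
  trial_sd = 0.3,
  n_trials = 8L)

# latent cognitive-domain levels (standardized composite scale)
scn_domain_reference <- list(
  memory = .ms(0.29, 0.78, 0.10, 0.71, -0.11, 0.78, -0.97, 0.73),
  language = .ms(0.21, 0.82, 0.24, 0.63, -0.31, 0.79, -0.59, 0.70),
  executive = .ms(0.10, 0.60, 0.28, 0.64, -0.15, 0.65, -0.56, 0.63))

# raw score scales for the individual tests: base level, slope against the
# latent domain level, and residual SD, all in plausible raw units
scn_test_reference <- data.frame(
  test = c("avlt_immediate", "avlt_short_delay", "avlt_long_delay",
           "avlt_cued", "avlt_recognition", "tmt_a", "tmt_b", "sdmt", "cdt",
           "aft", "bnt"),
  domain = c(rep("memory", 5), rep("executive", 4), "language", "language"),
  base = c(40, 8, 7, 8, 21, 55, 140, 35, 25, 17, 22),
  slope = c(8, 2.5, 2.5, 2.5, 2, -15, -35, 9, 3, 4, 4),
  resid = c(4, 1.5, 1.5, 1.5, 1.5, 10, 25, 5, 2, 2, 2),
  higher_is_better = c(rep(TRUE, 5), FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

# follow-up availability, conversion probability, and interval (days)
scn_followup_reference <- list(
  prob = c("NC" = 0, "G-SCD" = 20 / 40, "B-SCD" = 19 / 40, "MCI" = 0),
  conversion = c("NC" = 0, "G-SCD" = 0, "B-SCD" = 4 / 19, "MCI" = 0),
  interval = .ms(540, 160, 535.95, 163.50, 539.16, 168.55, 540, 160))
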