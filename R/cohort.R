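# Synthetic matched case-control cohorts with the published group
# structure: per-level trabecular BMD (Gaussian within group, exchangeable
# inter-level correlation), SAT/VAT volumes (zero-truncated Gaussian), and
# 1:1 age/follow-up matching.

#' Published group parameters of the matched case-control study
#'
#' Group means and SDs (control / incident-fracture) for trabecular BMD at
#' every vertebral level Th5-L5 (mg/cm^3), the QCT-standard L1-L3 mean,
#' and the L4/5 fat compartments (cm^3), as used to parameterize the
#' synthetic cohort generator and the AUC coverage simulations.
#'
#' @return Data frame with columns `variable`, `control_mean`, `control_sd`,
#'   `case_mean`, `case_sd`, `kind` (`"bmd"`, `"bmd_mean"` or `"fat"`).
#' @export
table1_parameters <- function() {
  data.frame(
    variable = c(vertebral_levels(), "L1L3", "VAT", "SAT", "VATSAT"),
    control_mean = c(176.4, 165.3, 166.3, 151.4, 158.9, 162.2, 154.0, 141.7,
                     136.8, 137.4, 127.1, 128.8, 133.3, 133.8, 266.3, 519.3, 0.6),
    control_sd = c(33.1, 39.7, 22.3, 30.4, 20.9, 29.7, 25.5, 26.9,
                   32.4, 32.6, 30.3, 31.7, 47.9, 29.4, 262.7, 339.8, 0.6),
    case_mean = c(142.2, 132.8, 128.4, 123.4, 124.1, 135.7, 129.4, 116.3,
                  115.1, 113.3, 111.9, 113.6, 117.9, 112.6, 245.0, 514.0, 0.5),
    case_sd = c(17.9, 32.5, 32.5, 27.6, 27.5, 27.4, 20.5, 16.0,
                25.1, 21.7, 19.7, 25.6, 40.1, 19.5, 260.2, 347.5, 0.5),
    kind = c(rep("bmd", 13), "bmd_mean", "fat", "fat", "fat_ratio"),
    stringsAsFactors = FALSE
  )
}

#' Cohort generator parameters
#'
#' @param params Per-variable group parameters in the layout of
#'   [table1_parameters()] (the default). Rows of kind `bmd` drive the
#'   13 correlated level draws; `VAT` and `SAT` rows drive the
#'   zero-truncated fat draws; `L1L3` and `VATSAT` rows are derived
#'   quantities in the generated cohort and are retained for reporting.
#' @param rho Exchangeable inter-level BMD correlation, `0 <= rho < 1`.
#' @param n_per_group Subjects per group.
#' @param age_mean,age_sd Pair-level age distribution (years).
#' @param followup_mean,followup_sd Pair-level follow-up (months).
#' @param match_jitter_sd Within-pair SD of age/follow-up (the matching
#'   tolerance).
#' @param n_prevalent Number of fracture-group subjects given a prevalent
#'   fracture at a random level (that level's BMD is missing, as it is not
#'   measured).
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(params = table1_parameters(), rho = 0.7,
                          n_per_group = 17L,
                          age_mean = 66.3, age_sd = 9.2,
                          followup_mean = 21.4, followup_sd = 11.5,
                          match_jitter_sd = 1, n_prevalent = 0L) {
  stopifnot(all(c("variable", "control_mean", "control_sd",
                  "case_mean", "case_sd") %in% names(params)))
  if (any(c(params$control_sd, params$case_sd) <= 0)) stop("SDs must be positive")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (n_per_group < 1L) stop("parameter error: n_per_group must be positive")
  if (!all(vertebral_levels() %in% params$variable))
    stop("params must include all 13 vertebral levels")
  structure(list(params = params, rho = rho,
                 n_per_group = as.integer(n_per_group),
                 age_mean = age_mean, age_sd = age_sd,
                 followup_mean = followup_mean, followup_sd = followup_sd,
                 match_jitter_sd = match_jitter_sd,
                 n_prevalent = as.integer(n_prevalent)),
            class = "cohort_params")
}

rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a matched case-control cohort
#'
#' One row per subject. BMD at the 13 levels is multivariate Gaussian
#' within group with an exchangeable correlation; the L1-L3 mean is
#' recomputed from the generated L1, L2, L3; VAT and SAT are independent
#' zero-truncated Gaussians and the VAT/SAT ratio is recomputed per
#' subject. Pair ids form a perfect 1:1 matching on age and follow-up
#' duration (pair-level values with a small within-pair jitter).
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed; generation is seed-reproducible.
#' @return Object of class `cohort_table` (a data frame): `subject_id`,
#'   `pair_id`, `group` (0 control / 1 fracture), `age`,
#'   `followup_months`, `Th5` .. `L5`, `L1L3`, `VAT`, `SAT`, `VATSAT`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(seed))
  lv <- vertebral_levels()
  p <- params$params
  n <- params$n_per_group
  S <- matrix(params$rho, 13, 13); diag(S) <- 1

  draw_group <- function(grp) {
    mcol <- if (grp == 0) "control_mean" else "case_mean"
    scol <- if (grp == 0) "control_sd" else "case_sd"
    pi <- p[match(lv, p$variable), ]
    z <- MASS::mvrnorm(n, mu = rep(0, 13), Sigma = S)
    bmd <- sweep(sweep(z, 2, pi[[scol]], "*"), 2, pi[[mcol]], "+")
    colnames(bmd) <- lv
    vat <- rnorm_trunc0(n, p[[mcol]][p$variable == "VAT"],
                        p[[scol]][p$variable == "VAT"])
    sat <- rnorm_trunc0(n, p[[mcol]][p$variable == "SAT"],
                        p[[scol]][p$variable == "SAT"])
    data.frame(group = grp, bmd, VAT = vat, SAT = sat,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  ctrl <- draw_group(0L)
  case <- draw_group(1L)

  pair_age <- stats::rnorm(n, params$age_mean, params$age_sd)
  pair_fu <- pmax(6, stats::rnorm(n, params$followup_mean, params$followup_sd))
  jit <- function() stats::rnorm(n, 0, params$match_jitter_sd)
  ctrl$age <- pair_age + jit();  case$age <- pair_age + jit()
  ctrl$followup_months <- pmax(6, pair_fu + jit())
  case$followup_months <- pmax(6, pair_fu + jit())
  ctrl$pair_id <- seq_len(n); case$pair_id <- seq_len(n)

  co <- rbind(ctrl, case)
  co$subject_id <- sprintf("S%03d", seq_len(nrow(co)))
  if (params$n_prevalent > 0L) {
    idx <- which(co$group == 1L)
    hit <- sample(idx, min(params$n_prevalent, length(idx)))
    for (s in hit) co[s, sample(lv, 1L)] <- NA_real_
  }
  co$L1L3 <- rowMeans(co[, c("L1", "L2", "L3")], na.rm = TRUE)
  co$L1L3[is.nan(co$L1L3)] <- NA_real_
  co$VATSAT <- ifelse(co$SAT > 0, co$VAT / co$SAT, NA_real_)
  co <- co[, c("subject_id", "pair_id", "group", "age", "followup_months",
               lv, "L1L3", "VAT", "SAT", "VATSAT")]
  class(co) <- c("cohort_table", "data.frame")
  co
}

#' Write / read a cohort table as CSV
#'
#' Plain RFC-4180-style CSV with a header row; missing BMD values (levels
#' with prevalent fractures are not measured) round-trip as empty cells.
#'
#' @param cohort A `cohort_table`.
#' @param path File path.
#' @return `read_cohort` returns a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        check.names = FALSE)
  class(co) <- c("cohort_table", "data.frame")
  co
}
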