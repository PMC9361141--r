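trial_strata <- as.vector(outer(c("female", "male"),
                                c("lt8", "s8_14", "ge15"), paste, sep = "."))

#' Stratified permuted-block randomization
#'
#' Assigns participants 1:1 to the intervention (`"SPA"`) and `"control"`
#' arms in permuted blocks of 4 within strata defined by sex crossed with
#' the baseline ISI group (`<8`, `8-14`, `>=15`). For each stratum a
#' seeded generator pre-draws a sequence of random permutations of
#' AABB-type blocks; participants are assigned by arrival order within
#' their stratum, so every complete block holds exactly `block_size/2` of
#' each arm, the allocation is reproducible under the seed, and relabeling
#' participants (keeping arrival order) does not change the arm sequence.
#'
#' @param roster A data frame with `participant_id`, `sex` (`"female"` /
#'   `"male"`), and `baseline_isi` (0..28), in arrival order.
#' @param block_size Block length (default 4); must be a multiple of the
#'   sum of `ratio`.
#' @param ratio Allocation ratio as an integer pair `c(SPA, control)`
#'   (default 1:1).
#' @param seed Integer seed; required, so allocations are auditable.
#' @return The roster tibble with added `stratum`, `arm`, and
#'   `block_index` (block number within stratum) columns.
#' @export
stratified_block_randomize <- function(roster, block_size = 4L,
                                       ratio = c(1L, 1L), seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(block_size %% sum(ratio) == 0)
  roster <- tibble::as_tibble(roster)
  if (!all(roster$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  cls <- isi_classify(roster$baseline_isi)
  roster$stratum <- paste(roster$sex, cls$stratum, sep = ".")
  if (!all(roster$stratum %in% trial_strata)) {
    stop("unknown stratum: ",
         paste(setdiff(roster$stratum, trial_strata), collapse = ", "),
         call. = FALSE)
  }
  arms <- rep(c("SPA", "control"), times = ratio * (block_size %/% sum(ratio)))
  roster$arm <- NA_character_
  roster$block_index <- NA_integer_
  for (k in seq_along(trial_strata)) {
    idx <- which(roster$stratum == trial_strata[k])
    if (!length(idx)) next
    n_blocks <- ceiling(length(idx) / block_size)
    # independent, reproducible substream per stratum
    seq_arms <- withr::with_seed(
      as.integer((as.numeric(seed) + 7919 * k) %% .Machine$integer.max),
      unlist(lapply(seq_len(n_blocks), function(b) sample(arms))))
    roster$arm[idx] <- seq_arms[seq_along(idx)]
    roster$block_index[idx] <-
      ((seq_along(idx) - 1L) %/% block_size) + 1L
  }
  roster
}

#' Sample size for a two-arm comparison of mean change
#'
#' The normal-approximation formula for two independent groups:
#' `n = ceil( 2 (z_{1-alpha/2} + z_{power})^2 sd^2 / delta^2 )` per group.
#' With the study's pilot inputs — a 1.3-point ISI reduction with SD 2.3,
#' two-sided alpha 0.05, 80% power — this gives 50 per group.
#'
#' @param delta Smallest effect to detect (points, > 0).
#' @param sd Outcome standard deviation (points, > 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Integer participants per group.
#' @export
required_sample_size <- function(delta, sd, alpha = 0.05, power = 0.80) {
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(2 * z^2 * sd^2 / delta^2))
}

#' Inflate an analysis sample size for expected attrition
#'
#' Uses the multiplicative convention `ceil(n * (1 + rate))`, under which a
#' 100-participant analysis target with 20% expected attrition becomes an
#' enrollment target of 120.
#'
#' @param n_total Required analyzable participants.
#' @param rate Expected attrition fraction in `[0, 1)`.
#' @return Integer enrollment target.
#' @export
inflate_for_attrition <- function(n_total, rate) {
  stopifnot(rate >= 0, rate < 1, n_total > 0)
  as.integer(ceiling(n_total * (1 + rate)))
}

#' Pearson chi-square test for a contingency table
#'
#' The plain Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the product of the margins, `df = (r-1)(c-1)`, and no continuity
#' correction for any table size (including 2x2) — the form used for the
#' trial's baseline comparisons.
#'
#' @param counts A matrix of non-negative integer counts with all row and
#'   column totals positive.
#' @return A list: `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0)) {
    stop("all row and column totals must be positive", call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  statistic <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       expected = expected)
}

#' Two-sample comparison of change scores
#'
#' Welch's two-sample t test on pre-post change scores, returning the mean
#' difference (a - b), its 95% confidence interval, and the two-sided p
#' value. Samples with zero variance in both groups are handled
#' degenerately rather than erroring: identical distributions give p = 1,
#' a pure constant shift gives the shift with p = 0.
#'
#' @param a,b Numeric vectors of change scores (each length >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `difference`, `conf_int`, `p_value`, `n`.
#' @export
two_sample_t_change <- function(a, b, conf_level = 0.95) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  d <- mean(a) - mean(b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(list(difference = d, conf_int = c(d, d),
                p_value = if (d == 0) 1 else 0,
                n = c(length(a), length(b))))
  }
  tt <- stats::t.test(a, b, conf.level = conf_level)
  list(difference = unname(d), conf_int = unname(tt$conf.int),
       p_value = tt$p.value, n = c(length(a), length(b)))
}

#' CONSORT flow accounting
#'
#' Tallies the participant flow of a two-arm trial and derives the per-arm
#' and overall dropout rates (participants excluded after allocation over
#' participants allocated, as a percentage to one decimal place).
#'
#' @param applied Number who applied / were assessed.
#' @param eligible Number eligible for allocation.
#' @param allocated Named integer vector of allocations per arm, e.g.
#'   `c(SPA = 62, control = 56)`.
#' @param dropouts Named integer vector of post-allocation exclusions per
#'   arm (same names as `allocated`).
#' @param dropout_reasons Optional character vector of reasons (length equal
#'   to total dropouts).
#' @return A list: `flow` (tibble of stage counts per arm),
#'   `dropout_rate` (named percents, 1 dp), `overall_dropout_rate`,
#'   `analyzed` (named counts).
#' @export
consort_accounting <- function(applied, eligible, allocated, dropouts,
                               dropout_reasons = NULL) {
  stopifnot(eligible <= applied, sum(allocated) <= eligible)
  if (!identical(sort(names(allocated)), sort(names(dropouts)))) {
    stop("'allocated' and 'dropouts' must name the same arms", call. = FALSE)
  }
  dropouts <- dropouts[names(allocated)]
  if (any(dropouts > allocated)) {
    stop("more exclusions than allocations in an arm (analyzed would ",
         "exceed allocated)", call. = FALSE)
  }
  analyzed <- allocated - dropouts
  rate <- round(100 * dropouts / allocated, 1)
  flow <- tibble::tibble(
    stage = c("applied", "eligible",
              paste0("allocated.", names(allocated)),
              paste0("excluded.", names(allocated)),
              paste0("analyzed.", names(allocated))),
    n = c(applied, eligible, unname(allocated), unname(dropouts),
          unname(analyzed))
  )
  list(flow = flow, dropout_rate = rate,
       overall_dropout_rate = round(100 * sum(dropouts) / sum(allocated), 1),
       analyzed = analyzed, dropout_reasons = dropout_reasons)
}
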