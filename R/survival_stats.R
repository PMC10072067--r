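#' Kaplan-Meier product-limit survival curve
#'
#' Hand-built product-limit estimator: at each distinct event time
#' `t_i` with `d_i` deaths among `n_i` flies at risk,
#' `S(t) = prod(1 - d_i / n_i)` over `t_i <= t`. Censored flies leave the
#' risk set after their censoring time (ties between deaths and censorings
#' at the same time keep the censored flies at risk for that time, the
#' usual convention).
#'
#' @param vitals Data frame with columns `lifespan_days` and `dead`
#'   (e.g. from [call_death()] / [score_cohort()]).
#' @return An object of class `km_curve`: a list with `time`, `n_risk`,
#'   `n_event`, `surv` (per distinct event time), `n`, `censor_times`,
#'   `median` and the genotype label when unique.
#' @export
km_estimate <- function(vitals) {
  if (is.null(vitals) || !nrow(vitals)) stop("Empty survival group.", call. = FALSE)
  time <- vitals$lifespan_days
  event <- as.logical(vitals$dead)
  stopifnot(length(time) == length(event), all(time >= 0))
  ev_times <- sort(unique(time[event]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(event & time == t), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  curve <- structure(
    list(
      time = ev_times, n_risk = n_risk, n_event = n_event, surv = surv,
      n = length(time),
      censor_times = sort(time[!event]),
      genotype = if (length(unique(vitals$genotype)) == 1L)
        vitals$genotype[1] else NA_character_
    ),
    class = "km_curve"
  )
  curve$median <- median_survival(curve)
  curve
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf(
    "<km_curve> %s: n = %d, %d events, median survival = %s days\n",
    ifelse(is.na(x$genotype), "group", x$genotype), x$n,
    as.integer(sum(x$n_event)),
    ifelse(is.na(x$median), "not reached", format(x$median))
  ))
  invisible(x)
}

#' Evaluate a KM curve at given times
#'
#' @param curve A `km_curve`.
#' @param t Times (days).
#' @return `S(t)` for each `t` (right-continuous step function, `S(0) = 1`).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- sum(curve$time <= tt)
    if (i == 0L) 1 else curve$surv[i]
  }, numeric(1))
}

#' Median survival from a KM curve
#'
#' The smallest event time at which the survival function drops to 0.5 or
#' below. When the curve sits exactly on an S = 0.5 plateau (common with
#' even group sizes) the default is still the first qualifying time;
#' `interpolate = TRUE` instead reports the midpoint between that time and
#' the next event time, matching the convention of common graphing
#' software and explaining fractional medians such as 22.5 days.
#'
#' @param curve A `km_curve`.
#' @param interpolate Midpoint rule on an exact 0.5 plateau
#'   (default `FALSE`).
#' @return Median survival in days, or `NA` if `S` never reaches 0.5.
#' @export
median_survival <- function(curve, interpolate = FALSE) {
  i <- which(curve$surv <= 0.5)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  med <- curve$time[i]
  if (interpolate && isTRUE(all.equal(curve$surv[i], 0.5)) &&
      i < length(curve$time)) {
    med <- (curve$time[i] + curve$time[i + 1L]) / 2
  }
  med
}

#' Two-group Mantel-Haenszel (log-rank) test
#'
#' The standard log-rank test as graphing software labels it
#' "Mantel-Haenszel": at each distinct event time `j` with `d_j` total
#' deaths among `n_j` at risk (`n_Aj` in group A), the observed group-A
#' deaths are compared with the hypergeometric expectation
#' `E_j = n_Aj d_j / n_j` and variance
#' `V_j = d_j (n_Aj / n_j)(1 - n_Aj / n_j)(n_j - d_j)/(n_j - 1)` (tie
#' corrected). The statistic `(sum(O - E))^2 / sum(V)` is chi-square with
#' 1 df. It is invariant to swapping the group labels and to any
#' monotone rescaling of the time axis.
#'
#' @param vitals_a,vitals_b Vitals data frames for the two groups
#'   (columns `lifespan_days`, `dead`).
#' @return A list: `chisq`, `df`, `p_value`, `observed`/`expected` per
#'   group, `n` per group.
#' @export
logrank_test <- function(vitals_a, vitals_b) {
  if (is.null(vitals_a) || !nrow(vitals_a) ||
      is.null(vitals_b) || !nrow(vitals_b)) {
    stop("Both survival groups must be non-empty.", call. = FALSE)
  }
  time <- c(vitals_a$lifespan_days, vitals_b$lifespan_days)
  event <- as.logical(c(vitals_a$dead, vitals_b$dead))
  in_a <- rep(c(TRUE, FALSE), c(nrow(vitals_a), nrow(vitals_b)))
  if (!any(event)) stop("No events in either group.", call. = FALSE)

  ev_times <- sort(unique(time[event]))
  o_a <- e_a <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n_aj <- sum(at_risk & in_a)
    d_j <- sum(event & time == t)
    d_aj <- sum(event & time == t & in_a)
    o_a <- o_a + d_aj
    e_a <- e_a + n_aj * d_j / n_j
    if (n_j > 1L) {
      v <- v + d_j * (n_aj / n_j) * (1 - n_aj / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  if (v <= 0) {
    chisq <- 0
  } else {
    chisq <- (o_a - e_a)^2 / v
  }
  d_total <- sum(event)
  list(
    chisq = chisq, df = 1L,
    p_value = if (chisq == 0) 1 else stats::pchisq(chisq, 1L, lower.tail = FALSE),
    observed = c(a = o_a, b = d_total - o_a),
    expected = c(a = e_a, b = d_total - e_a),
    n = c(a = nrow(vitals_a), b = nrow(vitals_b))
  )
}

#' Unpaired two-tailed Student t-test with degenerate fallback
#'
#' Pooled-variance Student test by default (Welch with
#' `var_equal = FALSE`). When both groups have zero variance but different
#' means, the t statistic is undefined; rather than dividing by zero a
#' label-permutation test on the mean difference is run (exhaustive when
#' feasible, otherwise Monte Carlo) and its p-value reported.
#'
#' @param x,y Numeric vectors.
#' @param var_equal Pooled-variance Student test (default `TRUE`).
#' @param n_perm Permutation budget for the degenerate fallback.
#' @return List: `t`, `df`, `p_value`, `method`.
#' @keywords internal
#' @export
student_t <- function(x, y, var_equal = TRUE, n_perm = 10000L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                method = "insufficient n"))
  }
  pooled_var <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (pooled_var == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1,
                  method = "student (degenerate, identical)"))
    }
    p <- permutation_mean_test(x, y, n_perm)
    return(list(t = NA_real_, df = NA_real_, p_value = p,
                method = "permutation (zero variance)"))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       method = if (var_equal) "student" else "welch")
}

# Two-sided permutation test on |mean(x) - mean(y)|; exhaustive when the
# number of reassignments is small, else Monte Carlo without replacement
# guarantees p >= 1/n_perm.
permutation_mean_test <- function(x, y, n_perm = 10000L) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x)
  n_comb <- choose(length(pool), nx)
  if (n_comb <= n_perm) {
    idx <- utils::combn(length(pool), nx)
    stat <- apply(idx, 2, function(i) abs(mean(pool[i]) - mean(pool[-i])))
    mean(stat >= obs - 1e-12)
  } else {
    stat <- replicate(n_perm, {
      i <- sample.int(length(pool), nx)
      abs(mean(pool[i]) - mean(pool[-i]))
    })
    (1 + sum(stat >= obs - 1e-12)) / (n_perm + 1)
  }
}

#' Eclosion (larva-to-adult survival) statistics
#'
#' Converts per-vial eclosion counts to percentages
#' (`100 * n_eclosed / n_input_larvae`), summarizes each genotype as
#' mean +/- sem over replicate vials (the vial is the unit of
#' replication), and runs unpaired two-tailed Student t-tests between all
#' genotype pairs on the replicate percentages. Genotypes with a single
#' replicate are summarized without a sem and skipped in tests, with a
#' warning.
#'
#' @param table Data frame with columns `genotype`, `replicate`,
#'   `n_input_larvae`, `n_eclosed`.
#' @param var_equal Passed to [student_t()].
#' @return List with `summary` (per genotype) and `tests` (per pair).
#' @export
eclosion_stats <- function(table, var_equal = TRUE) {
  req <- c("genotype", "replicate", "n_input_larvae", "n_eclosed")
  if (!all(req %in% names(table))) {
    stop("Eclosion table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$n_eclosed > table$n_input_larvae) ||
      any(table$n_eclosed < 0) || any(table$n_input_larvae <= 0)) {
    stop("Eclosion counts out of range.", call. = FALSE)
  }
  table$pct <- 100 * table$n_eclosed / table$n_input_larvae
  groups <- split(table$pct, table$genotype)
  summary <- data.frame(
    genotype = names(groups),
    n_replicates = vapply(groups, length, integer(1)),
    mean_pct_eclosed = vapply(groups, mean, numeric(1)),
    sem_pct_eclosed = vapply(groups, sem, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  singles <- summary$genotype[summary$n_replicates < 2L]
  if (length(singles)) {
    warning("Single-replicate genotype(s) skipped in tests: ",
            paste(singles, collapse = ", "), call. = FALSE)
  }
  gl <- setdiff(names(groups), singles)
  tests <- NULL
  if (length(gl) >= 2L) {
    pairs <- utils::combn(gl, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      tt <- student_t(groups[[a]], groups[[b]], var_equal = var_equal)
      data.frame(group_a = a, group_b = b, t = tt$t, df = tt$df,
                 p_value = tt$p_value, method = tt$method,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summary, tests = tests)
}

#' Compare per-unit counts between two groups
#'
#' Unpaired two-tailed Student t-test on per-unit values (haemocytes/mL
#' per larva, Repo+ cells per brain, ...). Groups with fewer than 2 units
#' report `NA` statistics.
#'
#' @param table Data frame with columns `genotype` and `value` (and
#'   optionally `unit_id`, `unit_kind`).
#' @param group_a,group_b Genotype labels to compare.
#' @param var_equal Passed to [student_t()].
#' @return One-row data frame: group means, sems, ns, `t`, `df`,
#'   `p_value`.
#' @export
count_compare <- function(table, group_a, group_b, var_equal = TRUE) {
  if (any(table$value < 0, na.rm = TRUE)) {
    stop("Count values must be non-negative.", call. = FALSE)
  }
  xa <- table$value[table$genotype == group_a]
  xb <- table$value[table$genotype == group_b]
  tt <- student_t(xa, xb, var_equal = var_equal)
  data.frame(
    group_a = group_a, group_b = group_b,
    mean_a = if (length(xa)) mean(xa, na.rm = TRUE) else NA_real_,
    sem_a = sem(xa[!is.na(xa)]), n_a = sum(!is.na(xa)),
    mean_b = if (length(xb)) mean(xb, na.rm = TRUE) else NA_real_,
    sem_b = sem(xb[!is.na(xb)]), n_b = sum(!is.na(xb)),
    t = tt$t, df = tt$df, p_value = tt$p_value, method = tt$method,
    stringsAsFactors = FALSE
  )
}

#' Haemocyte concentration from a haemocytometer count
#'
#' Converts a raw chamber count into cells per mL of haemolymph. Each
#' large haemocytometer square holds 0.1 uL, so cells/mL of the loaded
#' suspension is `count / n_squares * 1e4`; bleeding the larva into an
#' equal volume of trypan blue (10 uL haemolymph-in-PBS + 10 uL dye)
#' dilutes the haemolymph 1:1, hence the default dilution factor of 2.
#'
#' @param cells_counted Total cells counted.
#' @param n_squares Number of large squares counted (default 1).
#' @param dilution_factor Fold dilution of the haemolymph before loading
#'   (default 2 for the 1:1 trypan-blue mix).
#' @return Cells per mL of haemolymph.
#' @export
haemocyte_concentration <- function(cells_counted, n_squares = 1,
                                    dilution_factor = 2) {
  stopifnot(cells_counted >= 0, n_squares >= 1, dilution_factor >= 1)
  cells_counted / n_squares * 1e4 * dilution_factor
}
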