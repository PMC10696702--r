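#' 1:1 propensity-score matching of controls to cases
#'
#' Fits a logistic model of case status on the covariates over cases and the
#' control pool jointly, then greedily matches each case (in descending order
#' of case propensity, so the hardest-to-match cases pick first) to the
#' nearest unused control on the propensity scale, without replacement.
#'
#' @param cases,pool data.frames of cases and candidate controls, both
#'   containing the covariate columns and a `sample_id` column.
#' @param covariates character vector of covariate names (e.g. age and a
#'   numeric blood-collection time point).
#' @param caliper optional maximum propensity distance; pairs beyond it are
#'   left unmatched (default `NULL`: no caliper).
#' @return data.frame with `case_id`, `control_id`, `distance` (propensity
#'   difference) -- one row per matched case; matching is injective.
#' @export
propensity_match <- function(cases, pool, covariates, caliper = NULL) {
  if (nrow(pool) < nrow(cases)) stop("control pool smaller than case set")
  if (nrow(pool) == 0) stop("empty control pool")
  for (v in covariates) {
    if (!v %in% names(cases) || !v %in% names(pool))
      stop("covariate not present in both sets: ", v)
    if (all(is.na(cases[[v]])) || all(is.na(pool[[v]])))
      stop("covariate entirely missing: ", v)
  }
  df <- rbind(cbind(cases[covariates], .case = 1),
              cbind(pool[covariates], .case = 0))
  fit <- suppressWarnings(
    glm(.case ~ ., binomial(), data = df))
  ps <- fit$fitted.values
  ps_case <- ps[seq_len(nrow(cases))]
  ps_ctrl <- ps[-seq_len(nrow(cases))]
  used <- rep(FALSE, nrow(pool))
  ord <- order(ps_case, decreasing = TRUE)
  res <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    d <- abs(ps_ctrl - ps_case[i])
    d[used] <- Inf
    j <- which.min(d)
    if (!is.null(caliper) && d[j] > caliper) next
    used[j] <- TRUE
    res[[k]] <- data.frame(case_id = cases$sample_id[i],
                           control_id = pool$sample_id[j],
                           distance = d[j], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out[order(match(out$case_id, cases$sample_id)), , drop = FALSE]
}

#' Standardized mean difference of a covariate between matched groups
#'
#' @param x,y numeric vectors.
#' @return `|mean(x) - mean(y)| / sd_pooled`.
#' @export
standardized_mean_difference <- function(x, y) {
  sp <- sqrt((var(x) + var(y)) / 2)
  if (sp == 0) return(0)
  abs(mean(x) - mean(y)) / sp
}

#' Baseline characteristics comparison table
#'
#' For each continuous variable a normality screen (Shapiro-Wilk at
#' `alpha = 0.05`, per group) chooses the test: an independent t-test if
#' both groups look normal, a t-test on log-transformed values if both look
#' normal after log, otherwise a Mann-Whitney U-test (exact for
#' `min(n1, n2) <= 8` without ties, normal approximation with tie correction
#' otherwise -- the default behaviour of [stats::wilcox.test()]). Nominal
#' variables get a chi-square test on the contingency table. Optionally a
#' covariate-adjusted p-value is added per continuous variable from a linear
#' model of the (possibly log) response on group plus the covariate.
#'
#' @param data data.frame of variables.
#' @param group two-level factor/character vector of group labels.
#' @param variables continuous variable names (default: all numeric columns).
#' @param nominal nominal variable names tested by chi-square.
#' @param adjust_for optional single covariate name for adjusted p-values.
#' @return data.frame with one row per variable: test used, per-group
#'   mean +/- SE (or counts), `p_value`, `adjusted_p`, `skipped` flag.
#' @export
baseline_table <- function(data, group, variables = NULL, nominal = NULL,
                           adjust_for = NULL) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2)
  if (is.null(variables))
    variables <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                         c(nominal, adjust_for))
  rows <- list()
  for (v in variables) {
    x <- split(data[[v]], group)
    if (any(vapply(x, function(g) sum(!is.na(g)), 0) < 2)) {
      rows[[v]] <- baseline_row(v, "skipped", x, NA, NA, "fewer than 2 per group")
      next
    }
    if (any(vapply(x, function(g) var(g, na.rm = TRUE), 0) == 0)) {
      rows[[v]] <- baseline_row(v, "skipped", x, NA, NA, "zero variance")
      next
    }
    normal_raw <- all(vapply(x, function(g) shapiro.test(g)$p.value, 0) >= 0.05)
    can_log <- all(unlist(x) > 0, na.rm = TRUE)
    normal_log <- can_log &&
      all(vapply(x, function(g) shapiro.test(log(g))$p.value, 0) >= 0.05)
    if (normal_raw) {
      test <- "t"
      p <- t.test(x[[1]], x[[2]])$p.value
    } else if (normal_log) {
      test <- "t_on_log"
      p <- t.test(log(x[[1]]), log(x[[2]]))$p.value
    } else {
      test <- "mann_whitney"
      p <- suppressWarnings(wilcox.test(x[[1]], x[[2]]))$p.value
    }
    adj <- NA_real_
    if (!is.null(adjust_for) && adjust_for != v) {
      y <- if (test == "t_on_log") log(data[[v]]) else data[[v]]
      fit <- lm(y ~ group + data[[adjust_for]])
      adj <- summary(fit)$coefficients[2, 4]
    }
    rows[[v]] <- baseline_row(v, test, x, p, adj, NA_character_)
  }
  for (v in nominal) {
    tab <- table(data[[v]], group)
    p <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    rows[[v]] <- data.frame(
      variable = v, test = "chi_square",
      group1 = paste(tab[, 1], collapse = "/"),
      group2 = paste(tab[, 2], collapse = "/"),
      p_value = p, adjusted_p = NA_real_, skipped = NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

baseline_row <- function(v, test, x, p, adj, reason) {
  fmt <- function(g) {
    g <- g[!is.na(g)]
    sprintf("%.2f ± %.2f", mean(g), sd(g) / sqrt(length(g)))
  }
  data.frame(variable = v, test = test,
             group1 = fmt(x[[1]]), group2 = fmt(x[[2]]),
             p_value = p, adjusted_p = adj, skipped = reason,
             stringsAsFactors = FALSE)
}
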