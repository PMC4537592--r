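#' Multilevel piecewise path model fitting
#'
#' Component regressions are fitted by maximum likelihood (lme4 for mixed
#' models, OLS when a node has no random effects), the d-separation basis
#' set is tested claim by claim, and model support is summarised by
#' Fisher's C, the path-level AICc and Akaike weights.
#'
#' @name path_model
#' @keywords internal
NULL

#' Build the standardized analysis table
#'
#' Continuous variables are z-scored; age and stage become 0/1 indicators
#' with juvenile and coast as reference levels (so positive age and stage
#' coefficients mean adult and ocean effects); groundspeed is
#' log-transformed before scaling; `tailwind_sq` is the z-scored square of
#' the z-scored tailwind, the quadratic companion used by the duration
#' model.
#'
#' @param data data.frame with columns `age` ("adult"/"juvenile"), `stage`
#'   ("ocean"/"coast"), `tailwind`, `crosswind`, `duration_min`,
#'   `groundspeed_ms`, `nest_id`, `individual_id`.
#' @return data.frame with standardized columns `age`, `stage`,
#'   `tailwind`, `crosswind`, `tailwind_sq`, `flight_duration`,
#'   `log_groundspeed` plus the grouping factors.
#' @export
standardize_data <- function(data) {
  zs <- function(x, what) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("degenerate variable (zero variance): ", what, call. = FALSE)
    (x - mean(x)) / s
  }
  tw <- zs(data$tailwind, "tailwind")
  out <- data.frame(
    age = as.integer(data$age == "adult"),
    stage = as.integer(data$stage == "ocean"),
    tailwind = tw,
    crosswind = zs(data$crosswind, "crosswind"),
    tailwind_sq = zs(tw^2, "tailwind_sq"),
    flight_duration = zs(data$duration_min, "flight_duration"),
    log_groundspeed = zs(log(data$groundspeed_ms), "log_groundspeed"),
    nest_id = as.character(data$nest_id),
    individual_id = as.character(data$individual_id),
    stringsAsFactors = FALSE)
  if (length(unique(out$age)) < 2 || length(unique(out$stage)) < 2)
    stop("degenerate variable: age or stage has a single level",
         call. = FALSE)
  out
}

.component_formula <- function(dag, node) {
  rhs <- c(.parents(dag, node), dag$extra_terms[[node]])
  re <- dag$random[[node]]
  rhs <- c(if (length(rhs)) rhs else "1",
           if (length(re)) paste0("(1 | ", re, ")"))
  stats::as.formula(paste(node, "~", paste(rhs, collapse = " + ")))
}

.fit_ml <- function(formula, data) {
  mixed <- any(grepl("\\|", deparse(formula)))
  if (mixed) {
    fit <- tryCatch(
      lme4::lmer(formula, data = data, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      error = function(e) e)
    if (inherits(fit, "error")) {
      # random-effect structure unfittable: retreat to the fixed part
      message("mixed fit failed (", conditionMessage(fit),
              "); refitting without random effects")
      fixed <- stats::as.formula(
        paste(deparse(formula[[2]]), "~",
              paste(labels(stats::terms(lme4::nobars(formula))),
                    collapse = " + ")))
      if (!length(labels(stats::terms(lme4::nobars(formula)))))
        fixed <- stats::as.formula(paste(deparse(formula[[2]]), "~ 1"))
      fit <- stats::lm(fixed, data = data)
    }
    fit
  } else {
    stats::lm(formula, data = data)
  }
}

.fixef <- function(fit) if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)

.coef_table <- function(fit) {
  b <- .fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  data.frame(term = names(b), estimate = unname(b), se = unname(se),
             stringsAsFactors = FALSE)
}

.n_variance_params <- function(fit) {
  if (inherits(fit, "merMod"))
    length(lme4::VarCorr(fit)) + 1L   # one per random intercept + residual
  else 1L                             # residual variance
}

#' Fit all component regressions of a path diagram
#'
#' One ML fit per endogenous node: the node regressed on its parents (and
#' any extra interaction terms) with the node's random intercepts. Data
#' must already be standardized, so coefficients are standardized path
#' coefficients.
#'
#' @param dag A [path_dag()].
#' @param data Standardized analysis table ([standardize_data()]).
#' @param cache Optional environment memoising fits by formula (used by
#'   [backward_eliminate()], where candidate models share most component
#'   regressions).
#' @return Named list of component summaries: `formula`, `fit`, `coefs`
#'   (standardized estimates with SE), `loglik`, `k`.
#' @export
fit_components <- function(dag, data, cache = NULL) {
  out <- lapply(dag$endogenous, function(nd) {
    fml <- .component_formula(dag, nd)
    key <- paste(deparse(fml), collapse = "")
    if (!is.null(cache) && !is.null(cache[[key]])) {
      cm <- cache[[key]]; cm$node <- nd
      return(cm)
    }
    fit <- .fit_ml(fml, data)
    ll <- stats::logLik(fit)
    nfix <- length(.fixef(fit))
    cm <- list(node = nd, formula = fml, fit = fit,
               coefs = .coef_table(fit), loglik = as.numeric(ll),
               k = nfix + .n_variance_params(fit))
    if (!is.null(cache)) cache[[key]] <- cm
    cm
  })
  setNames(out, dag$endogenous)
}

#' Fisher's C from independence-claim p-values
#'
#' `C = -2 * sum(log p_i)`, chi-squared with `2 * length(p)` degrees of
#' freedom under the claimed model. Nonpositive p-values are clipped to
#' 1e-16 with a warning.
#'
#' @param p_values Numeric vector of p-values in (0, 1]; may be empty
#'   (saturated model, C = 0).
#' @return List with `C`, `df`, `p_value` (goodness-of-fit test).
#' @export
fishers_c <- function(p_values) {
  if (any(p_values <= 0)) {
    warning("nonpositive p-value(s) clipped to 1e-16", call. = FALSE)
    p_values <- pmax(p_values, 1e-16)
  }
  if (any(p_values > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  C <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  list(C = C, df = df,
       p_value = if (df) stats::pchisq(C, df, lower.tail = FALSE) else 1)
}

#' Path-level small-sample AICc
#'
#' `AICc = C + 2 K n / (n - K - 1)` with C Fisher's C, K the total
#' parameter count across component models and n the number of
#' observations (flight segments).
#'
#' @param C Fisher's C statistic.
#' @param K Total parameters.
#' @param n Observations.
#' @return AICc value.
#' @export
path_aicc <- function(C, K, n) {
  stopifnot(C >= 0, K > 0)
  if (n <= K + 1)
    stop("path AICc undefined: n must exceed K + 1", call. = FALSE)
  C + 2 * K * n / (n - K - 1)
}

.test_claim <- function(dag, data, x, y, conditioning, cache = NULL) {
  cond <- if (nzchar(conditioning))
    strsplit(conditioning, ",", fixed = TRUE)[[1]] else character(0)
  re <- dag$random[[y]]
  rhs <- c(sort(cond), x, if (length(re)) paste0("(1 | ", re, ")"))
  fml <- stats::as.formula(paste(y, "~", paste(rhs, collapse = " + ")))
  key <- paste("claim:", deparse(fml), collapse = "")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  fit <- .fit_ml(fml, data)
  b <- .fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  est <- b[[x]]; s <- se[[which(names(b) == x)]]
  df <- nrow(data) - length(b)   # between-within style residual df
  tval <- est / s
  res <- list(estimate = est, se = s, t = tval,
              p = 2 * stats::pt(-abs(tval), df))
  if (!is.null(cache)) cache[[key]] <- res
  res
}

#' Fit a full piecewise path model
#'
#' Fits the component regressions, tests every claim in the d-separation
#' basis set (two-sided Wald test on the added predictor, residual df
#' `n - p`), and assembles Fisher's C, K, and the path AICc.
#'
#' @param dag A [path_dag()].
#' @param data Standardized analysis table.
#' @param cache Optional memoisation environment (see
#'   [fit_components()]).
#' @return An object of class `path_fit`: `dag`, `components`, `claims`
#'   (with estimates and p-values), `C`, `C_df`, `C_p`, `K`, `n`, `aicc`,
#'   `coefficients` (stacked standardized coefficients).
#' @export
fit_path <- function(dag, data, cache = NULL) {
  comps <- fit_components(dag, data, cache = cache)
  bs <- basis_set(dag)
  claims <- bs
  if (nrow(bs)) {
    res <- lapply(seq_len(nrow(bs)), function(i)
      .test_claim(dag, data, bs$x[i], bs$y[i], bs$conditioning[i],
                  cache = cache))
    claims$estimate <- vapply(res, `[[`, 0, "estimate")
    claims$p <- vapply(res, `[[`, 0, "p")
  } else {
    claims$estimate <- numeric(0)
    claims$p <- numeric(0)
  }
  fc <- fishers_c(claims$p)
  K <- sum(vapply(comps, `[[`, 0, "k"))
  n <- nrow(data)
  coefs <- do.call(rbind, lapply(comps, function(cm) {
    cf <- cm$coefs
    cf$node <- cm$node
    cf
  }))
  rownames(coefs) <- NULL
  structure(list(dag = dag, components = comps, claims = claims,
                 C = fc$C, C_df = fc$df, C_p = fc$p_value,
                 K = K, n = n, aicc = path_aicc(fc$C, K, n),
                 coefficients = coefs),
            class = "path_fit")
}

#' Human-readable component equations of a path model
#'
#' @param x A [path_dag()] or `path_fit`.
#' @return Single string, component formulas separated by "; ",
#'   intercept-only components omitted.
#' @export
model_equations <- function(x) {
  dag <- if (inherits(x, "path_fit")) x$dag else x
  eq <- vapply(dag$endogenous, function(nd) {
    pa <- c(.parents(dag, nd), dag$extra_terms[[nd]])
    if (!length(pa)) return(NA_character_)
    paste(nd, "~", paste(pa, collapse = " + "))
  }, "")
  eq <- eq[!is.na(eq)]
  if (!length(eq)) "(intercept-only)" else paste(eq, collapse = "; ")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("path_fit:", model_equations(x), "\n")
  cat(sprintf("  Fisher's C = %.2f (df = %d, p = %.3f), K = %d, n = %d, AICc = %.2f\n",
              x$C, x$C_df, x$C_p, x$K, x$n, x$aicc))
  invisible(x)
}

#' Model selection table in the style of published path-AICc tables
#'
#' @param fits List of `path_fit` objects.
#' @return data.frame with `model_equations`, `K`, `AICc`, `dAICc`, `W`,
#'   `cumW`, `fishers_C`, sorted ascending by AICc; weights computed by
#'   [akaike_weights()].
#' @export
model_selection_table <- function(fits) {
  if (!length(fits)) stop("no fits to tabulate", call. = FALSE)
  tab <- data.frame(
    model_equations = vapply(fits, model_equations, ""),
    K = vapply(fits, `[[`, 0, "K"),
    AICc = vapply(fits, `[[`, 0, "aicc"),
    fishers_C = vapply(fits, `[[`, 0, "C"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$W <- akaike_weights(tab$AICc)
  tab$cumW <- cumsum(tab$W)
  rownames(tab) <- NULL
  tab[, c("model_equations", "K", "AICc", "dAICc", "W", "cumW", "fishers_C")]
}

#' Backward elimination of a path model by the two-unit AICc rule
#'
#' Starting from the full diagram, the two interaction terms are screened
#' first (each is dropped when its removal does not raise the path AICc by
#' at least 2). The main loop then removes edges greedily in two ordered
#' phases — edges into the wind components first, then edges into the
#' response — accepting at each step the removal with the lowest resulting
#' AICc, provided it does not exceed the current AICc by 2 or more. The
#' quadratic tailwind edge must leave before the linear tailwind edge can.
#' A null model (final model with all response edges removed) closes the
#' candidate set.
#'
#' @param data Standardized analysis table.
#' @param response Response node (`"flight_duration"` or
#'   `"log_groundspeed"`).
#' @param dag Starting diagram (default [full_flight_dag()]).
#' @param quadratic Include the quadratic tailwind edge in the full model
#'   (default TRUE).
#' @return List with `final` (`path_fit`), `table`
#'   ([model_selection_table()] over every distinct model visited), and
#'   `steps` (log of attempted removals).
#' @export
backward_eliminate <- function(data, response = "flight_duration",
                               dag = NULL, quadratic = TRUE) {
  if (is.null(dag)) dag <- full_flight_dag(response)
  if (!quadratic &&
      any(dag$edges$from == "tailwind_sq" & dag$edges$to == response))
    dag <- drop_edge(dag, "tailwind_sq", response)
  cache <- new.env(parent = emptyenv())
  visited <- list()
  steps <- list()
  remember <- function(fit) {
    key <- model_equations(fit)
    if (is.null(visited[[key]])) visited[[key]] <<- fit
    fit
  }
  current <- remember(fit_path(dag, data, cache = cache))

  # interaction pre-screen: removal changes K only (interactions are not
  # edges, so the basis set is untouched)
  for (term in rev(dag$extra_terms[[response]])) {
    trial_dag <- current$dag
    trial_dag$extra_terms[[response]] <-
      setdiff(trial_dag$extra_terms[[response]], term)
    trial <- remember(fit_path(trial_dag, data, cache = cache))
    accepted <- trial$aicc < current$aicc + 2
    steps[[length(steps) + 1]] <- list(phase = "interactions",
                                       removed = term,
                                       aicc = trial$aicc,
                                       accepted = accepted)
    if (accepted) current <- trial
  }

  removable <- function(dag, targets) {
    ed <- dag$edges[dag$edges$to %in% targets, , drop = FALSE]
    # linear tailwind is locked while its quadratic companion remains
    lock <- vapply(seq_len(nrow(ed)), function(i) {
      det <- names(dag$deterministic)[dag$deterministic == ed$from[i]]
      length(det) &&
        any(dag$edges$from %in% det & dag$edges$to == ed$to[i])
    }, TRUE)
    ed[!lock, , drop = FALSE]
  }

  for (phase in list(list(name = "wind", targets = c("tailwind", "crosswind")),
                     list(name = "response", targets = response))) {
    repeat {
      cand <- removable(current$dag, phase$targets)
      if (!nrow(cand)) break
      trials <- lapply(seq_len(nrow(cand)), function(i)
        remember(fit_path(drop_edge(current$dag, cand$from[i], cand$to[i]),
                          data, cache = cache)))
      aiccs <- vapply(trials, `[[`, 0, "aicc")
      i <- which.min(aiccs)
      accepted <- aiccs[i] < current$aicc + 2
      steps[[length(steps) + 1]] <- list(
        phase = phase$name,
        removed = paste(cand$from[i], "->", cand$to[i]),
        aicc = aiccs[i], accepted = accepted)
      if (!accepted) break
      current <- trials[[i]]
    }
  }

  # null model: the final model with every path into the response removed
  ed <- current$dag$edges
  null_dag <- path_dag(ed[ed$to != response, , drop = FALSE],
                       endogenous = current$dag$endogenous,
                       random = current$dag$random,
                       deterministic = current$dag$deterministic,
                       extra_terms = list(), nodes = current$dag$nodes)
  remember(fit_path(null_dag, data, cache = cache))

  list(final = current,
       table = model_selection_table(unname(visited)),
       steps = steps)
}
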