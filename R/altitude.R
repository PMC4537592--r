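#' Probing the atmosphere: per-level wind models and the AICc altitude scan
#'
#' For each flight stage, flight duration is modelled as a function of the
#' tailwind component, crosswind component, their interaction and a
#' quadratic tailwind term, using the wind measured at each atmospheric
#' level in turn. Within a level the best term subset is chosen by AICc;
#' across levels the level with the lowest AICc identifies the altitude at
#' which winds best explain flight performance — a proxy for the average
#' flight altitude of the stage.
#'
#' @name altitude_probe
#' @keywords internal
NULL

# Candidate fixed-effect term sets: the interaction only enters with both
# main effects, the quadratic only with the linear tailwind term.
.candidate_term_sets <- function() {
  list(character(0),
       "tailwind",
       "crosswind",
       c("tailwind", "crosswind"),
       c("tailwind", "crosswind", "tailwind:crosswind"),
       c("tailwind", "I(tailwind^2)"),
       c("tailwind", "crosswind", "I(tailwind^2)"),
       c("tailwind", "crosswind", "tailwind:crosswind", "I(tailwind^2)"))
}

.wind_formula <- function(response, terms, random_effects) {
  rhs <- c(terms, if (length(random_effects))
    paste0("(1 | ", random_effects, ")"))
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit one candidate wind model at one level
#'
#' Maximum-likelihood fit (never REML, so AICc is comparable across
#' fixed-effect structures) of `response ~ terms` with optional random
#' intercepts. Mixed models use lme4; models without random effects use
#' ordinary least squares. A zero-variance random effect is a valid ML
#' estimate and is retained; a fit that errors or yields a non-finite
#' log-likelihood is flagged (`ok = FALSE`) and later excluded from
#' selection.
#'
#' @param data data.frame holding the response, `tailwind`, `crosswind`
#'   and any random-effect grouping columns.
#' @param terms Character vector of fixed-effect terms (may be empty for
#'   the null model).
#' @param random_effects Character vector of grouping factors for random
#'   intercepts (e.g. `"nest_id"`), or empty.
#' @param response Response column name (default `"duration_min"`).
#' @param stage,level_id Labels carried through to the result.
#' @return A `candidate_model` list: terms, random effects, `loglik`, `k`,
#'   `n`, `aicc`, `ok`, plus the fitted model object.
#' @export
fit_candidate <- function(data, terms = character(0),
                          random_effects = character(0),
                          response = "duration_min",
                          stage = NA_character_, level_id = NA_character_) {
  y <- data[[response]]
  if (is.null(y)) stop("response column not found: ", response, call. = FALSE)
  if (stats::var(y) == 0)
    stop("degenerate fit: response has zero variance", call. = FALSE)
  fml <- .wind_formula(response, terms, random_effects)
  fit <- tryCatch({
    if (length(random_effects))
      lme4::lmer(fml, data = data, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    else
      stats::lm(fml, data = data)
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(stage = stage, level_id = level_id, terms = terms,
                          random_effects = random_effects,
                          loglik = NA_real_, k = NA_real_, n = nrow(data),
                          aicc = Inf, ok = FALSE,
                          message = conditionMessage(fit), model = NULL),
                     class = "candidate_model"))
  }
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- nrow(data)
  ok <- is.finite(as.numeric(ll)) && n > k + 1
  structure(list(stage = stage, level_id = level_id, terms = terms,
                 random_effects = random_effects,
                 loglik = as.numeric(ll), k = k, n = n,
                 aicc = if (ok) regression_aicc(as.numeric(ll), k, n) else Inf,
                 ok = ok, message = NULL, model = fit),
            class = "candidate_model")
}

#' Best term subset at one level by AICc
#'
#' Fits all admissible term subsets (interaction only with both mains,
#' quadratic only with linear tailwind) and returns the minimal-AICc
#' model. If no subset beats the null model (intercept plus random
#' effects) by at least 2 AICc units, the null is returned with
#' `informative = FALSE`.
#'
#' @inheritParams fit_candidate
#' @return The winning `candidate_model`, with an `informative` flag.
#' @export
best_subset_per_level <- function(data, random_effects = character(0),
                                  response = "duration_min",
                                  stage = NA_character_,
                                  level_id = NA_character_) {
  fits <- lapply(.candidate_term_sets(), fit_candidate, data = data,
                 random_effects = random_effects, response = response,
                 stage = stage, level_id = level_id)
  bad <- !vapply(fits, `[[`, TRUE, "ok")
  if (any(bad))
    warning(sum(bad), " candidate fit(s) failed at level ", level_id,
            " and were excluded", call. = FALSE)
  null_fit <- fits[[1]]
  if (!null_fit$ok)
    stop("null model failed to fit at level ", level_id, call. = FALSE)
  alt <- fits[-1][vapply(fits[-1], `[[`, TRUE, "ok")]
  if (length(alt)) {
    best <- alt[[which.min(vapply(alt, `[[`, 0, "aicc"))]]
    if (best$aicc <= null_fit$aicc - 2) {
      best$informative <- TRUE
      return(best)
    }
  }
  null_fit$informative <- FALSE
  null_fit
}

#' Scan atmospheric levels for the best wind altitude
#'
#' Joins each level's wind annotation to the stage's flight segments, runs
#' [best_subset_per_level()] per level, and selects the level whose best
#' model has the lowest AICc. The dAICc profile against altitude is the
#' stage's atmospheric probe; exact AICc ties are broken toward the lowest
#' altitude.
#'
#' @param segments Segment data.frame (see [segments_table()]).
#' @param annotations Long annotation data.frame from
#'   [annotate_segments()].
#' @param stage `"ocean"` or `"coast"`. By default ocean models carry a
#'   `nest_id` random intercept and coastal models do not.
#' @param random_effects Override the stage default.
#' @param response Response column in `segments` (default duration).
#' @return An `altitude_scan` object: `table` (per-level AICc profile),
#'   `selected_level`, `selected_altitude_m`, `models`, `stage`.
#' @export
altitude_scan <- function(segments, annotations, stage = c("ocean", "coast"),
                          random_effects = NULL,
                          response = "duration_min") {
  stage <- match.arg(stage)
  if (is.null(random_effects))
    random_effects <- if (stage == "ocean") "nest_id" else character(0)
  seg <- segments[segments$stage == stage, , drop = FALSE]
  ann <- annotations[annotations$stage == stage, , drop = FALSE]
  levels_here <- unique(ann$level_id)
  if (length(levels_here) < 2)
    stop("altitude scan needs at least 2 annotated levels", call. = FALSE)
  per_level <- lapply(levels_here, function(l) {
    a <- ann[ann$level_id == l, c("tag_id", "tailwind_ms", "crosswind_ms",
                                  "level_altitude_m")]
    d <- merge(seg, a, by = "tag_id")
    d$tailwind <- d$tailwind_ms
    d$crosswind <- d$crosswind_ms
    best <- best_subset_per_level(d, random_effects = random_effects,
                                  response = response, stage = stage,
                                  level_id = l)
    best$altitude_m <- a$level_altitude_m[1]
    best
  })
  tab <- data.frame(
    level_id = levels_here,
    altitude_m = vapply(per_level, `[[`, 0, "altitude_m"),
    terms = vapply(per_level, function(m)
      paste(m$terms, collapse = " + "), ""),
    k = vapply(per_level, `[[`, 0, "k"),
    n = vapply(per_level, `[[`, 0, "n"),
    loglik = vapply(per_level, `[[`, 0, "loglik"),
    aicc = vapply(per_level, `[[`, 0, "aicc"),
    informative = vapply(per_level, `[[`, TRUE, "informative"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$altitude_m), , drop = FALSE]
  rownames(tab) <- NULL
  tab$daicc <- tab$aicc - min(tab$aicc)
  if (!any(tab$informative)) {
    warning("all levels uninformative: returning null selection",
            call. = FALSE)
    sel <- NA_character_; sel_alt <- NA_real_
  } else {
    i <- which(tab$daicc == 0)[1]  # ties resolved toward the lowest altitude
    sel <- tab$level_id[i]; sel_alt <- tab$altitude_m[i]
  }
  structure(list(stage = stage, table = tab, selected_level = sel,
                 selected_altitude_m = sel_alt,
                 models = setNames(per_level, levels_here)),
            class = "altitude_scan")
}

#' @export
print.altitude_scan <- function(x, ...) {
  cat(sprintf("altitude scan (%s stage): selected level %s (%.0f m)\n",
              x$stage, x$selected_level, x$selected_altitude_m))
  print(x$table[, c("level_id", "altitude_m", "terms", "aicc", "daicc",
                    "informative")], digits = 5)
  invisible(x)
}

#' Plot the dAICc-against-altitude profile of an altitude scan
#'
#' @param x An `altitude_scan` object (or list of them, overlaid).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_altitude_scan <- function(x, ...) {
  scans <- if (inherits(x, "altitude_scan")) list(x) else x
  xs <- unlist(lapply(scans, function(s) s$table$altitude_m))
  ys <- unlist(lapply(scans, function(s) s$table$daicc))
  graphics::plot(NA, xlim = range(xs), ylim = range(ys),
                 xlab = "altitude (m)", ylab = expression(Delta * "AICc"),
                 ...)
  for (i in seq_along(scans)) {
    tb <- scans[[i]]$table
    graphics::lines(tb$altitude_m, tb$daicc, lty = i)
    graphics::points(tb$altitude_m, tb$daicc, pch = c(1, 0, 2)[1 + (i - 1) %% 3])
  }
  invisible(NULL)
}
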