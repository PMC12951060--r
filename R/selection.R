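#' Prepare candidate predictors for model selection
#'
#' Drops zero-variance (degenerate) columns and, when present, the
#' uninformative order-0 amplitude/phase columns, with a message listing
#' what was removed. Run before any search.
#'
#' @param features data frame of candidate predictors.
#' @param quiet suppress the message.
#' @return data frame of usable candidates.
#' @export
prepare_candidates <- function(features, quiet = FALSE) {
  stopifnot(is.data.frame(features))
  keep_num <- vapply(features, is.numeric, logical(1))
  dropped_nonnum <- names(features)[!keep_num]
  features <- features[, keep_num, drop = FALSE]
  v <- vapply(features, function(x) stats::var(x), numeric(1))
  degenerate <- names(features)[!is.finite(v) | v < 1e-24]
  zero_order <- intersect(names(features),
                          c("dC0", "dP0", "absdC0", "absdP0",
                            "dC0CV", "dP0CV", "absdC0CV", "absdP0CV"))
  drop <- union(c(dropped_nonnum, degenerate), zero_order)
  if (length(drop) && !quiet)
    message("dropping degenerate/uninformative candidates: ",
            paste(sort(drop), collapse = ", "))
  features[, setdiff(names(features), drop), drop = FALSE]
}

# fit a candidate variable set; +Inf AIC when unusable (separation,
# singularity, non-convergence, or a numerically singular information
# matrix leaving Wald SEs undefined), so searches never move there
try_fit <- function(features, vars, labels) {
  f <- tryCatch(
    fit_logistic(features[, vars, drop = FALSE], labels),
    error = function(e) NULL)
  if (is.null(f) || !f$converged || !all(is.finite(f$standard_errors)))
    return(list(model = NULL, aic = Inf))
  list(model = f, aic = f$aic)
}

# pick the AIC-minimizing move; ties broken toward removals (fewer
# parameters), then lexicographically by variable name
best_move <- function(aics) {
  ok <- is.finite(aics)
  if (!any(ok)) return(NULL)
  best <- min(aics[ok])
  cand <- names(aics)[ok & aics <= best + 1e-9]
  cand[order(substr(cand, 1L, 1L) != "-", substring(cand, 2L))][1L]
}

greedy_search <- function(features, labels, start_vars, can_add, can_drop,
                          method) {
  vars <- start_vars
  cur <- try_fit(features, vars, labels)
  if (is.null(cur$model))
    stop("starting model unfittable")  # callers handle backward fallback
  traj <- data.frame(step = 0L, action = "start",
                     variable = NA_character_, aic = cur$aic,
                     stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    moves <- c(
      if (can_add) {
        adds <- setdiff(colnames(features), vars)
        stats::setNames(
          vapply(adds, function(v)
            try_fit(features, c(vars, v), labels)$aic, numeric(1)),
          if (length(adds)) paste0("+", adds) else character(0))
      },
      if (can_drop && length(vars)) {
        stats::setNames(
          vapply(vars, function(v)
            try_fit(features, setdiff(vars, v), labels)$aic, numeric(1)),
          paste0("-", vars))
      })
    if (!length(moves)) break
    mv <- best_move(moves)
    if (is.null(mv) || moves[[mv]] >= cur$aic - 1e-8) break
    step <- step + 1L
    action <- substr(mv, 1L, 1L)
    v <- substring(mv, 2L)
    vars <- if (action == "+") c(vars, v) else setdiff(vars, v)
    cur <- try_fit(features, vars, labels)
    traj <- rbind(traj, data.frame(
      step = step, action = if (action == "+") "add" else "drop",
      variable = v, aic = cur$aic, stringsAsFactors = FALSE))
  }
  structure(list(method = method, candidates = colnames(features),
                 selected = sort(vars), model = cur$model,
                 trajectory = traj),
            class = "model_search")
}

#' Forward AIC selection
#'
#' Starts from the intercept-only model and greedily adds the variable
#' whose inclusion most lowers the AIC, while any addition strictly
#' lowers it. Ties are broken lexicographically by variable name, so the
#' search is deterministic.
#'
#' @param features data frame of candidate predictors (pass through
#'   [prepare_candidates()] first).
#' @param labels logical or 0/1 outcome vector.
#' @return object of class `model_search`: list with `method`,
#'   `candidates`, `selected` (sorted), `model` (a `fitted_model`) and
#'   `trajectory` (one row per accepted move with its AIC).
#' @export
forward_select <- function(features, labels) {
  greedy_search(features, labels, character(0), TRUE, FALSE, "forward")
}

#' Backward AIC elimination
#'
#' Starts from the full candidate model and greedily removes the variable
#' whose exclusion most lowers the AIC. When the full model cannot be
#' fitted (separation or a singular design, common when candidates
#' outnumber events), falls back to forward selection with a warning.
#'
#' @inheritParams forward_select
#' @return a `model_search` (with `method = "backward"`, or the forward
#'   fallback result carrying a `fallback` flag).
#' @export
backward_eliminate <- function(features, labels) {
  res <- tryCatch(
    greedy_search(features, labels, colnames(features), FALSE, TRUE,
                  "backward"),
    error = function(e) NULL)
  if (is.null(res)) {
    warning("full model unfittable; backward elimination falling back to forward selection",
            call. = FALSE)
    res <- forward_select(features, labels)
    res$method <- "backward"
    res$fallback <- TRUE
  }
  res
}

#' Stepwise (bidirectional) AIC selection
#'
#' Starts empty and at each step takes the single addition or removal
#' that most lowers the AIC, until no move lowers it. Ties are broken
#' toward removals (fewer parameters), then lexicographically.
#'
#' @inheritParams forward_select
#' @return a `model_search`.
#' @export
stepwise_select <- function(features, labels) {
  greedy_search(features, labels, character(0), TRUE, TRUE, "stepwise")
}

#' Run the configured searches and keep every result
#'
#' @param features candidate data frame.
#' @param labels outcome vector.
#' @param methods subset of `c("forward", "backward", "stepwise")`.
#' @return named list of `model_search` objects.
#' @export
run_searches <- function(features, labels,
                         methods = c("forward", "backward", "stepwise")) {
  methods <- match.arg(methods, several.ok = TRUE)
  fns <- list(forward = forward_select, backward = backward_eliminate,
              stepwise = stepwise_select)
  stats::setNames(lapply(methods, function(m) fns[[m]](features, labels)),
                  methods)
}

#' Select the minimum-AIC model among search results
#'
#' Ties are broken toward the model with fewer parameters, then
#' lexicographically by the sorted selected-variable names.
#'
#' @param fits non-empty list of `model_search` results (each with a
#'   converged `fitted_model`).
#' @return the winning `model_search`.
#' @export
select_best <- function(fits) {
  fits <- Filter(function(f) !is.null(f$model), fits)
  if (!length(fits)) stop("no converged fits to select from")
  aic <- vapply(fits, function(f) f$model$aic, numeric(1))
  k <- vapply(fits, function(f) f$model$k, numeric(1))
  key <- vapply(fits, function(f) paste(f$selected, collapse = ","),
                character(1))
  ord <- order(round(aic, 9), k, key)
  fits[[ord[1L]]]
}
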