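#' A candidate hyperparameter setting with its objective values
#'
#' Pairs a named hyperparameter setting with the vector of objective values
#' it achieved and the optimization direction of each objective. The Pareto
#' machinery is generic: any named parameters and any number of objectives.
#'
#' @param params named list of hyperparameter values.
#' @param objectives finite numeric vector of objective values.
#' @param directions character vector, one of `"minimize"`/`"maximize"` per
#'   objective (recycled if length 1).
#' @return object of class `objective_point`.
#' @export
objective_point <- function(params, objectives,
                            directions = "minimize") {
  objectives <- as.numeric(objectives)
  if (length(objectives) == 0L || any(!is.finite(objectives)))
    stop("objectives must be finite and non-empty", call. = FALSE)
  if (length(directions) == 1L)
    directions <- rep(directions, length(objectives))
  if (length(directions) != length(objectives) ||
      !all(directions %in% c("minimize", "maximize")))
    stop("directions must be minimize/maximize, one per objective",
         call. = FALSE)
  structure(list(params = params, objectives = objectives,
                 directions = directions),
            class = "objective_point")
}

# objectives recast so that smaller is always better
minimized <- function(p) {
  ifelse(p$directions == "maximize", -p$objectives, p$objectives)
}

#' Pareto dominance test
#'
#' `p` dominates `q` when it is at least as good in every objective (per
#' its direction) and strictly better in at least one.
#'
#' @param p,q [objective_point()]s with identical directions.
#' @return logical.
#' @export
dominates <- function(p, q) {
  if (length(p$objectives) != length(q$objectives) ||
      !identical(p$directions, q$directions))
    stop("points must share objectives and directions", call. = FALSE)
  a <- minimized(p); b <- minimized(q)
  all(a <= b) && any(a < b)
}

#' Extract the Pareto front
#'
#' Returns exactly the non-dominated subset of the candidates, preserving
#' input order; candidates with identical objective vectors are all
#' retained (none dominates the other).
#'
#' @param points non-empty list of [objective_point()]s with consistent
#'   directions.
#' @return list of the non-dominated points.
#' @export
pareto_front <- function(points) {
  if (!is.list(points) || length(points) == 0L)
    stop("pareto_front needs at least one candidate", call. = FALSE)
  obj <- do.call(rbind, lapply(points, minimized))
  n <- nrow(obj)
  keep <- vapply(seq_len(n), function(i) {
    le <- obj <= matrix(obj[i, ], n, ncol(obj), byrow = TRUE)
    lt <- obj < matrix(obj[i, ], n, ncol(obj), byrow = TRUE)
    dominated_by <- rowSums(le) == ncol(obj) & rowSums(lt) > 0
    !any(dominated_by[-i])
  }, logical(1))
  points[keep]
}

#' Weighted scalarization of two minimize-directed objectives
#'
#' Scores each candidate as `alpha * f1' + beta * f2'` where `f1'`, `f2'`
#' are the two objectives min-max normalized over the candidate set
#' (objective order: quality/loss first, model size second). Normalization
#' is essential when mixing a loss on the unit scale with parameter counts
#' in the millions. A constant objective normalizes to 0 for every
#' candidate.
#'
#' @param points list of [objective_point()]s with exactly two
#'   minimize-directed objectives.
#' @param alpha weight on the first objective, >= 0.
#' @param beta weight on the second objective, >= 0; `alpha + beta > 0`.
#' @return numeric vector of scalarized scores, one per candidate.
#' @export
scalarize <- function(points, alpha, beta) {
  if (!is.list(points) || length(points) == 0L)
    stop("scalarize needs at least one candidate", call. = FALSE)
  if (alpha < 0 || beta < 0 || alpha + beta <= 0)
    stop("alpha and beta must be >= 0 and not both zero", call. = FALSE)
  ok <- vapply(points, function(p)
    length(p$objectives) == 2L && all(p$directions == "minimize"),
    logical(1))
  if (!all(ok))
    stop("scalarize needs exactly two minimize-directed objectives",
         call. = FALSE)
  obj <- do.call(rbind, lapply(points, `[[`, "objectives"))
  norm <- apply(obj, 2L, function(col) {
    rng <- range(col)
    if (diff(rng) == 0) rep(0, length(col))
    else (col - rng[1]) / diff(rng)
  })
  norm <- matrix(norm, nrow = length(points))
  as.numeric(alpha * norm[, 1] + beta * norm[, 2])
}

#' Select the best trade-off configuration
#'
#' Restricts the candidates to the Pareto front (normalizing objectives
#' over the full candidate set first), then returns the front member with
#' the lowest scalarized score; ties are broken by the lower first
#' objective, then by input order. A dominated candidate can never be
#' selected, whatever its scalarized score.
#'
#' @inheritParams scalarize
#' @return the selected [objective_point()].
#' @export
select_config <- function(points, alpha, beta) {
  scores <- scalarize(points, alpha, beta)
  front_idx <- which(vapply(seq_along(points), function(i) {
    !any(vapply(seq_along(points)[-i], function(j)
      dominates(points[[j]], points[[i]]), logical(1)))
  }, logical(1)))
  f1 <- vapply(points, function(p) p$objectives[1], numeric(1))
  ord <- order(scores[front_idx], f1[front_idx], front_idx)
  points[[front_idx[ord[1]]]]
}

#' Read / write candidate lists as JSON
#'
#' JSON schema: an array of objects with fields `params` (object),
#' `objectives` (array of numbers) and `directions` (array of strings).
#'
#' @param path JSON file path.
#' @return `read_candidates`: list of [objective_point()]s.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path))
    stop("cannot read candidates: no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r)
    objective_point(r$params, unlist(r$objectives),
                    unlist(r$directions %||% "minimize")))
}

#' @rdname read_candidates
#' @param points list of [objective_point()]s.
#' @export
write_candidates <- function(points, path) {
  out <- lapply(points, function(p)
    list(params = p$params, objectives = p$objectives,
         directions = p$directions))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
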