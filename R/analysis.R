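## Solver-facing analyses on a GENRE: flux balance analysis (FBA),
## parsimonious FBA, GPR evaluation, single-gene deletion screening and
## seeded hit-and-run flux sampling.

#' Flux balance analysis
#'
#' Maximises flux through the objective reaction subject to steady state
#' (S v = 0) and the model's flux bounds.
#'
#' @param model a \code{genre} (media applied beforehand via
#'   \code{\link{set_media}}).
#' @param objective objective reaction id; defaults to the model's.
#' @return a \code{flux_distribution}: named \code{flux} vector,
#'   \code{objective_value}, and solver \code{status} ("optimal" or a
#'   failure label; objective_value is NA unless optimal).
#' @export
fba <- function(model, objective = model$objective) {
  S <- as.matrix(stoich_matrix(model))
  bnd <- reaction_bounds(model)
  obj <- as.numeric(names(model$reactions) == objective)
  if (!any(obj > 0)) stop("objective reaction '", objective, "' not in model")
  sol <- solve_lp(obj, A_eq = S, b_eq = rep(0, nrow(S)),
                  lb = bnd$lb, ub = bnd$ub, maximize = TRUE)
  flux <- stats::setNames(sol$x, names(model$reactions))
  structure(list(flux = flux,
                 objective_value = if (sol$status == "optimal") sol$objval else NA_real_,
                 status = sol$status),
            class = "flux_distribution")
}

#' Parsimonious FBA
#'
#' Two stages: an FBA fixes the attainable optimum z*, then a second LP
#' minimises total absolute flux (via nonnegative forward/reverse variable
#' splitting) subject to the objective flux staying at or above
#' \code{fraction * z*}.  Models the assumption that high flux means costly
#' enzyme turnover, so of all optimal-growth states the cell realises a
#' minimal-flux one.
#'
#' @param model a \code{genre}.
#' @param fraction fraction of the FBA optimum the objective must retain
#'   (default 1.0).
#' @return a \code{flux_distribution} whose \code{objective_value} is the
#'   objective reaction's flux and with an extra \code{total_flux} field
#'   (the minimised sum of absolute fluxes).
#' @export
pfba <- function(model, fraction = 1.0) {
  wt <- fba(model)
  if (wt$status != "optimal")
    return(structure(list(flux = wt$flux, objective_value = NA_real_,
                          total_flux = NA_real_, status = wt$status),
                     class = "flux_distribution"))
  zstar <- wt$objective_value
  sol <- .min_weighted_flux(model, weights = rep(1, length(model$reactions)),
                            floor_value = fraction * zstar)
  structure(list(flux = sol$flux, objective_value = sol$flux[[model$objective]],
                 total_flux = sol$objval, status = sol$status),
            class = "flux_distribution")
}

## Shared split-variable LP: minimise sum_r w_r (v_r+ + v_r-) subject to
## S v = 0, bounds, and v_objective >= floor_value.
.min_weighted_flux <- function(model, weights, floor_value) {
  S <- as.matrix(stoich_matrix(model))
  bnd <- reaction_bounds(model)
  n <- ncol(S)
  ## variables: p (forward) then n (reverse); v = p - n
  Aeq <- cbind(S, -S)
  beq <- rep(0, nrow(S))
  lb <- rep(0, 2 * n)
  ub <- c(pmax(bnd$ub, 0), pmax(-bnd$lb, 0))
  obj <- c(weights, weights)
  io <- match(model$objective, names(model$reactions))
  ## v_obj >= floor: -(p_obj - n_obj) <= -floor
  Ale <- matrix(0, 1, 2 * n)
  Ale[1, io] <- -1; Ale[1, n + io] <- 1
  sol <- solve_lp(obj, A_eq = Aeq, b_eq = beq, A_le = Ale,
                  b_le = -floor_value, lb = lb, ub = ub)
  if (sol$status != "optimal")
    return(list(flux = stats::setNames(rep(NA_real_, n),
                                       names(model$reactions)),
                objval = NA_real_, status = sol$status,
                activity = rep(NA_real_, n)))
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  list(flux = stats::setNames(v, names(model$reactions)),
       objval = sol$objval, status = "optimal",
       activity = sol$x[seq_len(n)] + sol$x[n + seq_len(n)])
}

## ---- GPR logic ----

#' Parse a gene-protein-reaction rule
#'
#' Grammar: gene ids combined with \code{and}/\code{or} (case-insensitive)
#' and parentheses; the empty rule is allowed.  AND encodes a required
#' complex, OR isozymes.
#'
#' @param gpr rule string.
#' @return parse tree (nested list with node types "and"/"or"/"gene"), or
#'   \code{NULL} for an empty rule; malformed rules raise an error.
#' @export
parse_gpr <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(NULL)
  toks <- regmatches(gpr, gregexpr("\\(|\\)|[^()\\s]+", gpr, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      node <- list(op = "or", args = list(node, parse_term()))
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      node <- list(op = "and", args = list(node, parse_factor()))
    }
    node
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("malformed GPR '", gpr, "': unexpected end")
    if (t == "(") {
      node <- parse_expr()
      if (!identical(take(), ")"))
        stop("malformed GPR '", gpr, "': missing ')'")
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed GPR '", gpr, "': unexpected '", t, "'")
    list(op = "gene", id = t)
  }
  tree <- parse_expr()
  if (!is.na(peek()))
    stop("malformed GPR '", gpr, "': trailing input at '", peek(), "'")
  tree
}

#' Gene ids appearing in a GPR rule
#' @param gpr rule string.
#' @return character vector (possibly empty).
#' @export
gpr_genes <- function(gpr) {
  tree <- parse_gpr(gpr)
  walk <- function(node) {
    if (is.null(node)) return(character())
    if (node$op == "gene") return(node$id)
    unlist(lapply(node$args, walk))
  }
  unique(walk(tree))
}

#' Evaluate a GPR rule under gene knockouts
#'
#' Substitutes FALSE for knocked-out genes and TRUE otherwise.  The empty
#' rule is always active (spontaneous / orphan reactions survive any
#' knockout).
#'
#' @param gpr rule string.
#' @param knocked character vector of knocked-out gene ids.
#' @return logical: is the reaction still catalysable?
#' @export
evaluate_gpr <- function(gpr, knocked = character()) {
  tree <- parse_gpr(gpr)
  if (is.null(tree)) return(TRUE)
  ev <- function(node) {
    switch(node$op,
           gene = !(node$id %in% knocked),
           and = ev(node$args[[1]]) && ev(node$args[[2]]),
           or = ev(node$args[[1]]) || ev(node$args[[2]]))
  }
  ev(tree)
}

#' Single-gene deletion (essentiality) screen
#'
#' For each gene, reactions whose GPR evaluates inactive under that single
#' knockout are constrained to zero flux and growth is recomputed by FBA.
#' A gene is essential when the knockout optimum falls below
#' \code{threshold_fraction} of the wild-type optimum.
#'
#' @param model a \code{genre} with media applied.
#' @param threshold_fraction growth fraction below which a gene is called
#'   essential (default 0.01, i.e. < 1 percent of wild type).
#' @return data.frame: gene, growth (knockout optimum), essential (logical).
#' @export
single_gene_deletion <- function(model, threshold_fraction = 0.01) {
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 0)
    stop("wild-type model does not grow; essentiality is undefined")
  zstar <- wt$objective_value
  genes <- genre_genes(model)
  growth <- vapply(genes, function(g) {
    km <- model
    for (id in names(km$reactions)) {
      r <- km$reactions[[id]]
      if (nzchar(r$gpr) && !evaluate_gpr(r$gpr, knocked = g)) {
        km$reactions[[id]]$lb <- 0
        km$reactions[[id]]$ub <- 0
      }
    }
    ko <- fba(km)
    if (ko$status == "optimal") ko$objective_value else 0
  }, 0)
  data.frame(gene = genes, growth = unname(growth),
             essential = unname(growth) < threshold_fraction * zstar,
             row.names = NULL, stringsAsFactors = FALSE)
}

## ---- flux sampling ----

#' Sample steady-state flux distributions
#'
#' Seeded hit-and-run walk over the steady-state polytope
#' \{v : S v = 0, lb <= v <= ub\}: movement directions are drawn in the
#' null space of S, so every sample satisfies mass balance by construction.
#' The walk starts from a most-interior point (an LP maximising the smallest
#' slack to any bound), discards a fixed warm-up of 100 steps and keeps
#' every 10th step thereafter.  The contract is feasibility plus
#' reproducibility under a fixed seed; statistical uniformity is not
#' asserted.
#'
#' @param model a \code{genre} with media applied.
#' @param n number of samples.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param warmup,thin warm-up steps and thinning interval.
#' @return matrix with one row per sample, one column per reaction.
#' @export
sample_fluxes <- function(model, n, seed, warmup = 100L, thin = 10L) {
  S <- as.matrix(stoich_matrix(model))
  bnd <- reaction_bounds(model)
  nr <- ncol(S)
  ## most-interior start: max s subject to S v = 0, lb + s <= v <= ub - s
  obj <- c(rep(0, nr), -1)
  Aeq <- cbind(S, 0)
  span <- bnd$ub - bnd$lb
  smax <- max(span) / 2
  Ale <- rbind(cbind(diag(nr), 1), cbind(-diag(nr), 1))
  ble <- c(bnd$ub, -bnd$lb)
  sol <- solve_lp(obj, A_eq = Aeq, b_eq = rep(0, nrow(S)), A_le = Ale,
                  b_le = ble, lb = c(bnd$lb, 0), ub = c(bnd$ub, smax))
  if (sol$status != "optimal")
    stop("flux sampling: steady-state region is empty (status ",
         sol$status, ")")
  v0 <- sol$x[seq_len(nr)]

  ## null space of S: directions that preserve mass balance exactly
  sv <- svd(S, nu = 0, nv = nr)
  d <- sv$d
  rank <- sum(d > max(dim(S)) * max(d, 0) * 1e-12)
  Nbasis <- if (rank < nr) sv$v[, seq.int(rank + 1L, nr), drop = FALSE] else
    matrix(0, nr, 0)

  samples <- matrix(v0, nrow = n, ncol = nr, byrow = TRUE,
                    dimnames = list(NULL, names(model$reactions)))
  if (ncol(Nbasis) == 0L) return(samples)  # single-point region

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))
  v <- v0
  kept <- 0L
  step <- 0L
  pad <- 1e-9
  max_steps <- warmup + 50L * thin * n
  while (kept < n) {
    step <- step + 1L
    if (step > max_steps) {  # region is (numerically) a point in most directions
      samples[seq.int(kept + 1L, n), ] <- matrix(v, n - kept, nr, byrow = TRUE)
      break
    }
    dir <- as.numeric(Nbasis %*% stats::rnorm(ncol(Nbasis)))
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-12) next
    dir <- dir / nd
    ## admissible step interval from the box bounds
    tmax <- Inf; tmin <- -Inf
    up <- dir > 1e-12; dn <- dir < -1e-12
    if (any(up)) {
      tmax <- min(tmax, (bnd$ub[up] - v[up]) / dir[up])
      tmin <- max(tmin, (bnd$lb[up] - v[up]) / dir[up])
    }
    if (any(dn)) {
      tmax <- min(tmax, (bnd$lb[dn] - v[dn]) / dir[dn])
      tmin <- max(tmin, (bnd$ub[dn] - v[dn]) / dir[dn])
    }
    if (!is.finite(tmax) || !is.finite(tmin) || tmax - tmin < pad) next
    ## never clamp v componentwise: that would leave the null space of S
    t <- stats::runif(1, tmin, tmax)
    v <- v + t * dir
    if (step > warmup && (step - warmup) %% thin == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- v
    }
  }
  samples
}
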