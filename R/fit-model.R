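#' Fit a GY94 codon model by maximum likelihood
#'
#' The central fitting routine behind the selection tests. Three model
#' families are supported:
#' \describe{
#'   \item{`"M0"`}{one dN/dS ratio shared by every branch.}
#'   \item{`"branch"`}{one dN/dS ratio per branch class of the labeled tree
#'     (e.g. background / flightless / flying).}
#'   \item{`"branch_site"`}{the 4-site-class branch-site mixture: a fraction
#'     of sites may switch to `omega2` on foreground (class > 0) branches;
#'     fixing `omega2 = 1` gives the null of the positive-selection test.}
#' }
#' Optimization is bounded quasi-Newton (`L-BFGS-B`) on log-transformed rate
#' parameters with optional jittered multi-starts; the branch-site mixture
#' weights are profiled out by an inner EM over the two mixture proportions.
#'
#' @param alignment a `codon_alignment`.
#' @param tree a `labeled_tree` (a plain `phylo` is treated as one class).
#' @param model `"M0"`, `"branch"` or `"branch_site"`.
#' @param freqs codon frequency model (`"F3x4"` default, `"F1x4"`, `"equal"`)
#'   or an explicit frequency vector.
#' @param fixed named list of parameters to hold fixed: any of `kappa`,
#'   `omega` (vector over branch classes), `omega0`, `omega2`, `scale`.
#' @param branch_lengths `"fixed"` uses the tree's lengths as given;
#'   `"scale"` additionally estimates one proportional scaling factor for the
#'   whole tree. Per-branch re-estimation is deliberately not offered: nested
#'   model comparisons share one branch-length treatment.
#' @param n_restarts number of optimizer starts (first heuristic, the rest
#'   jittered); deterministic given `seed`.
#' @param seed integer seed controlling the jittered restarts.
#' @param inits optional named list of natural-scale starting values (any of
#'   `kappa`, `omega` vector, `omega0`, `omega2`, `scale`) replacing the
#'   heuristic first start — used e.g. to start an alternative model from its
#'   null's optimum.
#' @param control passed to [stats::optim()] (merged over defaults).
#' @return an object of class `codon_fit` with components `lnL`, `kappa`,
#'   `omega` (per class, or the branch-site quadruple), `scale`, `freqs`,
#'   `converged`, `n_restarts_used`, `np` (free parameter count) and the
#'   scaled tree. Methods: `print`, `summary`, `coef`, `logLik`, `anova`,
#'   `simulate`.
#' @export
fit_codon_model <- function(alignment, tree,
                            model = c("M0", "branch", "branch_site"),
                            freqs = "F3x4", fixed = list(),
                            branch_lengths = c("fixed", "scale"),
                            n_restarts = 3L, seed = NULL, inits = NULL,
                            control = list()) {
  model <- match.arg(model)
  branch_lengths <- match.arg(branch_lengths)
  if (!inherits(tree, "labeled_tree")) tree <- labeled_tree(tree)
  prep <- prepare_pruning(alignment, tree)
  freq_model <- if (is.character(freqs)) freqs else "explicit"
  if (is.character(freqs)) freqs <- codon_frequencies(alignment, freqs, prep$code)
  freqs <- validate_freqs(freqs, length(prep$gc$codons))

  nclass <- max(prep$edge.class) + 1L
  bounds <- list(kappa = log(c(0.01, 100)), omega = log(c(1e-4, 999)),
                 omega0 = c(log(1e-4), 0), omega2 = c(0, log(999)),
                 scale = log(c(0.01, 100)))

  # Assemble the free-parameter template -------------------------------------
  par_names <- character(0)
  if (is.null(fixed$kappa)) par_names <- c(par_names, "kappa")
  if (model %in% c("M0", "branch")) {
    n_om <- if (model == "M0") 1L else nclass
    if (is.null(fixed$omega)) par_names <- c(par_names, paste0("omega", seq_len(n_om) - 1L))
  } else {
    if (is.null(fixed$omega0)) par_names <- c(par_names, "w0")
    if (is.null(fixed$omega2)) par_names <- c(par_names, "w2")
  }
  if (branch_lengths == "scale" && is.null(fixed$scale)) par_names <- c(par_names, "scale")

  lower <- upper <- stats::setNames(numeric(length(par_names)), par_names)
  for (nm in par_names) {
    b <- if (nm == "kappa") bounds$kappa
    else if (nm == "scale") bounds$scale
    else if (nm == "w0") bounds$omega0
    else if (nm == "w2") bounds$omega2
    else bounds$omega
    lower[nm] <- b[1]; upper[nm] <- b[2]
  }

  n_eval <- 0L
  mix <- NULL   # records EM solution of the last (best) evaluation

  unpack <- function(theta) {
    g <- function(nm, fx) if (nm %in% par_names) exp(theta[[nm]]) else fx
    kappa <- g("kappa", fixed$kappa)
    scale <- if (branch_lengths == "scale") g("scale", fixed$scale %||% 1) else 1
    if (model %in% c("M0", "branch")) {
      n_om <- if (model == "M0") 1L else nclass
      omega <- if (is.null(fixed$omega))
        exp(unlist(theta[paste0("omega", seq_len(n_om) - 1L)]))
      else rep_len(fixed$omega, n_om)
      list(kappa = kappa, omega = unname(omega), scale = scale)
    } else {
      list(kappa = kappa, omega0 = g("w0", fixed$omega0),
           omega2 = g("w2", fixed$omega2), scale = scale)
    }
  }

  negll <- function(theta) {
    theta <- as.list(stats::setNames(theta, par_names))
    p <- unpack(theta)
    n_eval <<- n_eval + 1L
    if (model %in% c("M0", "branch")) {
      om_edge <- if (model == "M0") matrix(p$omega[1], length(prep$lens), 1)
      else omega_matrix_branch(prep, p$omega)
      ll <- pattern_loglik(prep, p$kappa, freqs, om_edge, p$scale)
      -mix_loglik(ll, 1, prep$wts)
    } else {
      ll <- pattern_loglik(prep, p$kappa, freqs,
                           omega_matrix_branch_site(prep, p$omega0, p$omega2),
                           p$scale, ref_omega = p$omega0)
      em <- em_branch_site(ll, prep$wts)
      mix <<- em
      -em$lnL
    }
  }

  init0 <- c(kappa = log(2), scale = log(1),
             stats::setNames(rep(log(0.2), nclass), paste0("omega", seq_len(nclass) - 1L)),
             w0 = log(0.2), w2 = log(2.5))
  if (!is.null(inits)) {
    if (!is.null(inits$kappa)) init0["kappa"] <- log(inits$kappa)
    if (!is.null(inits$scale)) init0["scale"] <- log(inits$scale)
    if (!is.null(inits$omega))
      init0[paste0("omega", seq_along(inits$omega) - 1L)] <- log(inits$omega)
    if (!is.null(inits$omega0)) init0["w0"] <- log(inits$omega0)
    if (!is.null(inits$omega2)) init0["w2"] <- log(inits$omega2)
    init0 <- pmin(pmax(init0, -Inf), Inf)
  }
  init0[par_names] <- pmin(pmax(init0[par_names], lower), upper)
  starts <- list(init0[par_names])
  if (n_restarts > 1L) {
    jit <- with_seed(seed, lapply(seq_len(n_restarts - 1L), function(i)
      pmin(pmax(init0[par_names] + stats::rnorm(length(par_names), 0, 0.75),
                lower), upper)))
    starts <- c(starts, jit)
  }

  ctrl <- utils::modifyList(list(maxit = 300, factr = 1e8), control)
  best <- NULL
  for (st in starts) {
    fit <- if (length(par_names) == 0L) {
      list(par = numeric(0), value = negll(numeric(0)), convergence = 0L)
    } else {
      stats::optim(st, negll, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = ctrl)
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # re-evaluate at the optimum so `mix` matches the returned parameters
  best$value <- negll(best$par)

  p <- unpack(as.list(stats::setNames(best$par, par_names)))
  out <- list(call = match.call(), model = model, lnL = -best$value,
              kappa = p$kappa, scale = p$scale,
              freq_model = freq_model, freqs = freqs,
              branch_lengths = branch_lengths,
              np = length(par_names) + if (model == "branch_site") 2L else 0L,
              converged = best$convergence == 0L,
              n_restarts_used = length(starts), n_eval = n_eval,
              nclass = nclass, tree = tree,
              n_taxa = length(alignment$taxa), n_sites = alignment$sites)
  if (model %in% c("M0", "branch")) {
    out$omega <- stats::setNames(p$omega, paste0("class", seq_along(p$omega) - 1L))
  } else {
    out$omega <- c(omega0 = p$omega0, omega2 = p$omega2)
    out$p0 <- mix$p[1]; out$p1 <- mix$p[2]
    out$site_class_probs <- branch_site_probs(mix$p[1], mix$p[2])
  }
  class(out) <- "codon_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Profile the branch-site mixture weights (p0, p1) out of the likelihood.
# The four class weights factor as (s, 1-s) x (r, 1-r) over two independent
# binary latents, so EM has closed-form updates.
em_branch_site <- function(ll, wts, tol = 1e-9, maxit = 200L) {
  mx <- apply(ll, 1, max)
  L <- exp(ll - mx)                       # npat x 4, scaled
  r <- 0.7; s <- 0.85
  lnL_old <- -Inf
  W <- sum(wts)
  for (it in seq_len(maxit)) {
    w <- c(s * r, s * (1 - r), (1 - s) * r, (1 - s) * (1 - r))
    num <- L %*% w
    lnL <- sum(wts * (log(num) + mx))
    g <- (L * rep(w, each = nrow(L))) / as.vector(num)   # responsibilities
    r <- sum(wts * (g[, 1] + g[, 3])) / W
    s <- sum(wts * (g[, 1] + g[, 2])) / W
    if (lnL - lnL_old < tol && it > 3L) break
    lnL_old <- lnL
  }
  w <- c(s * r, s * (1 - r), (1 - s) * r, (1 - s) * (1 - r))
  lnL <- sum(wts * (log(L %*% w) + mx))
  list(lnL = lnL, p = c(p0 = s * r, p1 = s * (1 - r)), iterations = it)
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("GY94 codon model fit (", x$model, ")\n", sep = "")
  cat("  lnL = ", format(x$lnL, digits = 10), "  (", x$np, " free parameters",
      if (!x$converged) ", NOT converged" else "", ")\n", sep = "")
  cat("  kappa =", format(x$kappa, digits = 4),
      " scale =", format(x$scale, digits = 4), "\n")
  if (x$model == "branch_site") {
    cat("  omega0 =", format(x$omega[["omega0"]], digits = 4),
        " omega2 =", format(x$omega[["omega2"]], digits = 4),
        " p0 =", format(x$p0, digits = 4), " p1 =", format(x$p1, digits = 4), "\n")
  } else {
    cat("  omega:", paste(names(x$omega), format(x$omega, digits = 4),
                          sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
coef.codon_fit <- function(object, ...) {
  out <- c(kappa = object$kappa, object$omega, scale = object$scale)
  if (object$model == "branch_site") out <- c(out, p0 = object$p0, p1 = object$p1)
  out
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$np, nobs = object$n_sites, class = "logLik")
}

#' @export
summary.codon_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.codon_fit")
}

#' @export
print.summary.codon_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat("  data:", f$n_taxa, "taxa x", f$n_sites, "codon sites;",
      f$nclass, "branch class(es)\n")
  cat("  frequency model:", f$freq_model,
      "; branch lengths:", f$branch_lengths, "\n")
  cat("  optimizer evaluations:", f$n_eval, "over", f$n_restarts_used, "start(s)\n")
  invisible(x)
}

#' Likelihood-ratio comparison of nested codon model fits
#'
#' @param object the null (smaller) fit.
#' @param ... exactly one alternative fit.
#' @param df degrees of freedom for the chi-square reference; default the
#'   difference in free parameter counts.
#' @return a data.frame with lnL values, 2*Delta lnL (clamped at 0), df, and
#'   the chi-square p-value.
#' @export
anova.codon_fit <- function(object, ..., df = NULL) {
  alt <- list(...)[[1]]
  stopifnot(inherits(alt, "codon_fit"))
  if (is.null(df)) df <- abs(alt$np - object$np)
  lrt <- max(0, 2 * (alt$lnL - object$lnL))
  data.frame(lnL_null = object$lnL, lnL_alt = alt$lnL, lrt = lrt, df = df,
             p = stats::pchisq(lrt, df, lower.tail = FALSE))
}

#' Simulate alignments from a fitted codon model
#'
#' @param object a `codon_fit`.
#' @param nsim number of alignments.
#' @param seed integer seed.
#' @param nsites codon sites per alignment (default: the fitted data's size).
#' @param ... unused.
#' @return a list of `codon_alignment` objects (length `nsim`).
#' @export
simulate.codon_fit <- function(object, nsim = 1, seed = NULL, nsites = NULL, ...) {
  nsites <- nsites %||% object$n_sites
  tr <- object$tree
  tr$edge.length <- tr$edge.length * object$scale
  model <- if (object$model == "branch_site") {
    list(type = "branch_site", kappa = object$kappa, freqs = object$freqs,
         omega0 = object$omega[["omega0"]], omega2 = object$omega[["omega2"]],
         p0 = object$p0, p1 = object$p1)
  } else {
    list(type = "branch", kappa = object$kappa, freqs = object$freqs,
         omega = as.numeric(object$omega))
  }
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_codon_alignment(tr, model, nsites)))
}
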