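#' Run a replicated simulation benchmark
#'
#' The evaluation harness for the planted-eigenvector benchmark: for each
#' replicate it samples a dataset from the design, fits the requested
#' methods, and records
#'
#' * **angles** (methods `pca`, `ica`, `ipca`): the sign-invariant angle
#'   between planted eigenvector j and the method's j-th loading vector,
#'   j = 1, 2, matched *by index* after each method's own ordering
#'   (variance order for PCA, kurtosis order for ICA/IPCA);
#' * **loading kurtosis** (same methods): excess kurtosis of the first
#'   `ncomp_kurtosis` loading vectors;
#' * **identification rates** (methods `spca`, `sipca`): the percentage of
#'   each planted support recovered by the corresponding sparse component,
#'   with the two fitted components assigned to the two planted
#'   eigenvectors by best fit (smallest total angle) — extraction order of
#'   a near-degenerate eigenvalue pair is unstable under sampling noise,
#'   so support recovery is scored against the process a component
#'   actually captures.
#'
#' Angle fits use `ncomp` components (default 2); the kurtosis table uses
#' `ncomp_kurtosis` components (default 5; ICA whitens on the same number).
#' All randomness derives from `seed`: replicate i runs in a stream seeded
#' `seed + i`. FastICA inside the harness uses simulation-scale defaults
#' (`tol = 1e-4`, `max_iter = 200`, one restart); override via
#' `fastica_options`.
#'
#' @param design a [sim_design()] object.
#' @param methods subset of `c("pca", "ica", "ipca", "spca", "sipca")`.
#' @param n_reps number of replicate datasets.
#' @param ncomp components for angle/selection fits.
#' @param ncomp_kurtosis components for the kurtosis table; `NULL` skips it.
#' @param keepX variables kept per component for the sparse methods
#'   (broadcast if length 1).
#' @param seed integer master seed.
#' @param fastica_options list overriding `contrast`, `tol`, `max_iter`,
#'   `n_restarts`.
#' @param keep_replicates keep the per-replicate values (needed to
#'   recompute any aggregate; default TRUE).
#' @return an object of class `replicate_report`: `replicates` (tibble with
#'   columns `replicate`, `method`, `metric`, `component`, `value`),
#'   `summary` (per method x metric x component: n, mean, sd, median), the
#'   design and run settings, and `n_failed` (replicates excluded due to
#'   errors).
#' @examples
#' rep <- run_replicates(sim_design("sparse_gaussian", p = 100),
#'                       methods = "sipca", n_reps = 3, keepX = 10, seed = 1)
#' rep$summary
#' @export
run_replicates <- function(design,
                           methods = c("pca", "ica", "ipca"),
                           n_reps = 100,
                           ncomp = 2,
                           ncomp_kurtosis = if (any(methods %in% c("pca", "ica", "ipca"))) 5 else NULL,
                           keepX = 50,
                           seed = 1,
                           fastica_options = list(),
                           keep_replicates = TRUE) {
  stopifnot(inherits(design, "sim_design"))
  methods <- match.arg(methods, c("pca", "ica", "ipca", "spca", "sipca"),
                       several.ok = TRUE)
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  ncomp <- check_count(ncomp, "ncomp", min = 2L, max = min(design$n, design$p))
  if (!is.null(ncomp_kurtosis)) {
    ncomp_kurtosis <- check_count(ncomp_kurtosis, "ncomp_kurtosis", min = 2L,
                                  max = min(design$n, design$p))
  }
  fo <- modifyList(list(contrast = "logcosh", tol = 1e-4, max_iter = 200,
                        n_restarts = 1), fastica_options)
  if (length(keepX) == 1L) keepX <- rep(keepX, ncomp)
  seed <- check_count(seed, "seed", min = 0L)

  nk <- max(ncomp, ncomp_kurtosis %||% 0L)
  rows <- vector("list", n_reps)
  n_failed <- 0L
  n_nonconverged <- 0L
  for (i in seq_len(n_reps)) {
    res <- tryCatch(
      withCallingHandlers(
        with_seed(seed + i, {
          ds <- sim_dataset(design, seed = NULL)
          replicate_metrics(ds, methods, ncomp, ncomp_kurtosis, keepX, fo, nk)
        }),
        warning = function(w) {
          if (grepl("did not converge", conditionMessage(w))) {
            n_nonconverged <<- n_nonconverged + 1L
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    res$replicate <- i
    rows[[i]] <- res
  }
  if (n_failed > 0L) {
    warn(sprintf("%d of %d replicates failed and were excluded.", n_failed,
                 n_reps))
  }
  reps <- dplyr::bind_rows(rows)
  reps <- reps[, c("replicate", "method", "metric", "component", "value")]
  summary <- reps |>
    dplyr::group_by(.data$method, .data$metric, .data$component) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     median = stats::median(.data$value),
                     .groups = "drop")
  structure(
    list(replicates = if (keep_replicates) tibble::as_tibble(reps) else NULL,
         summary = summary, design = design, methods = methods,
         n_reps = n_reps, n_failed = n_failed,
         n_nonconverged = n_nonconverged, ncomp = ncomp,
         ncomp_kurtosis = ncomp_kurtosis, keepX = keepX, seed = seed,
         fastica_options = fo),
    class = "replicate_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## metrics for one simulated dataset; runs inside the replicate's RNG stream
replicate_metrics <- function(ds, methods, ncomp, ncomp_kurtosis, keepX, fo,
                              nk) {
  xc <- sweep(ds$data, 2, colMeans(ds$data), `-`)
  sv <- svd(xc, nu = nk, nv = nk)
  v1 <- ds$true_v1; v2 <- ds$true_v2
  out <- list()
  add <- function(method, metric, component, value) {
    out[[length(out) + 1L]] <<- data.frame(
      method = method, metric = metric, component = component, value = value)
  }

  if ("pca" %in% methods) {
    add("pca", "angle", 1:2, c(loading_angle(v1, sv$v[, 1]),
                               loading_angle(v2, sv$v[, 2])))
    if (!is.null(ncomp_kurtosis)) {
      add("pca", "kurtosis", seq_len(ncomp_kurtosis),
          apply(sv$v[, seq_len(ncomp_kurtosis), drop = FALSE], 2,
                kurtosis_excess))
    }
  }
  if ("ipca" %in% methods) {
    fit <- ipca_core(xc, ncomp = ncomp, contrast = fo$contrast, tol = fo$tol,
                     max_iter = fo$max_iter, n_restarts = fo$n_restarts,
                     seed = NULL, sv = sv)
    add("ipca", "angle", 1:2, c(loading_angle(v1, fit$loadings[, 1]),
                                loading_angle(v2, fit$loadings[, 2])))
    if (!is.null(ncomp_kurtosis)) {
      fit5 <- if (ncomp_kurtosis == ncomp) fit else {
        ipca_core(xc, ncomp = ncomp_kurtosis, contrast = fo$contrast,
                  tol = fo$tol, max_iter = fo$max_iter,
                  n_restarts = fo$n_restarts, seed = NULL, sv = sv)
      }
      add("ipca", "kurtosis", seq_len(ncomp_kurtosis), fit5$kurtosis)
    }
  }
  if ("ica" %in% methods) {
    nw <- ncomp_kurtosis %||% ncomp
    fit <- ica_core(xc, ncomp = nw, n_whiten = nw, contrast = fo$contrast,
                    tol = fo$tol, max_iter = fo$max_iter,
                    n_restarts = fo$n_restarts, seed = NULL, sv = sv)
    add("ica", "angle", 1:2, c(loading_angle(v1, fit$loadings[, 1]),
                               loading_angle(v2, fit$loadings[, 2])))
    if (!is.null(ncomp_kurtosis)) {
      add("ica", "kurtosis", seq_len(ncomp_kurtosis),
          fit$loading_kurtosis[seq_len(ncomp_kurtosis)])
    }
  }
  if ("spca" %in% methods) {
    fit <- spca_core(xc, ncomp = ncomp, keepX = keepX)
    sel <- best_assignment(fit$loadings[, 1:2], v1, v2)
    add("spca", "id_rate", 1:2,
        c(identification_rate(ds$support1, fit$selected[[sel[1]]]),
          identification_rate(ds$support2, fit$selected[[sel[2]]])))
  }
  if ("sipca" %in% methods) {
    core <- ipca_core(xc, ncomp = ncomp, contrast = fo$contrast,
                      tol = fo$tol, max_iter = fo$max_iter,
                      n_restarts = fo$n_restarts, seed = NULL, sv = sv)
    sel <- best_assignment(core$loadings[, 1:2], v1, v2)
    sel1 <- sparsify_exact(core$loadings[, sel[1]], keepX[1])$keep
    sel2 <- sparsify_exact(core$loadings[, sel[2]], keepX[2])$keep
    add("sipca", "id_rate", 1:2,
        c(identification_rate(ds$support1, sel1),
          identification_rate(ds$support2, sel2)))
  }
  do.call(rbind, out)
}

## joint assignment of two estimated loading columns to (v1, v2) by
## smallest total angle
best_assignment <- function(loadings, v1, v2) {
  a11 <- loading_angle(v1, loadings[, 1]); a22 <- loading_angle(v2, loadings[, 2])
  a12 <- loading_angle(v2, loadings[, 1]); a21 <- loading_angle(v1, loadings[, 2])
  if (a11 + a22 <= a12 + a21) c(1L, 2L) else c(2L, 1L)
}

#' @export
print.replicate_report <- function(x, ...) {
  cat(sprintf("replicate report: %s, %d replicate(s), methods: %s\n",
              x$design$case, x$n_reps, paste(x$methods, collapse = ", ")))
  if (x$n_failed > 0) cat(sprintf("  %d failed replicate(s) excluded\n", x$n_failed))
  print(x$summary, n = Inf)
  invisible(x)
}
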