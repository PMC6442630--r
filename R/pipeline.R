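# End-to-end orchestration: spectral clustering of a labeled graph, the
# Monte-Carlo two-truths experiment, the two-block projection EDA
# coordinates, and the Chernoff-ratio parameter map.

#' Spectral clustering of a graph
#'
#' The full pipeline `GMM o {LSE, ASE}` for one graph: spectral embedding
#' (at a fixed dimension or with automatic profile-likelihood selection),
#' Gaussian-mixture fitting (at a fixed number of clusters or with BIC
#' selection), and MAP assignment. If the graph is disconnected, its largest
#' connected component is analyzed, with a warning.
#'
#' @param g A [tt_graph()].
#' @param method `"ASE"` or `"LSE"`.
#' @param d Embedding dimension, or `"auto"` for profile-likelihood
#'   selection.
#' @param K Number of clusters, or `"auto"` for BIC selection.
#' @param seed Integer seed for the GMM initializations.
#' @param max_d Spectrum length for automatic dimension selection.
#' @param elbow Profile-likelihood elbow index.
#' @param K_range Candidate cluster counts for BIC selection.
#' @param n_init Random GMM restarts.
#' @return A list of class `tt_spectral_clustering`: `clustering` (a
#'   `tt_clustering` over the analyzed vertices), `diagnostics` (`d`, `K`,
#'   eigenvalues, BIC trace if selected, the embedding), and `index_map`
#'   (original vertex id to analyzed id, `NA` for vertices outside the
#'   largest connected component).
#' @export
spectral_cluster_graph <- function(g, method = c("ASE", "LSE"), d = "auto",
                                   K = "auto", seed = 1L, max_d = NULL,
                                   elbow = 1L, K_range = 1:50,
                                   n_init = 5L) {
  method <- match.arg(method)
  stopifnot(inherits(g, "tt_graph"))
  lcc <- largest_connected_component(g)
  if (lcc$graph$n < g$n) {
    warning("graph is disconnected; clustering its largest connected ",
            "component (", lcc$graph$n, " of ", g$n, " vertices)")
  }
  gg <- lcc$graph
  emb <- if (identical(d, "auto")) {
    embed_auto(gg, method, max_d = max_d, elbow = elbow)
  } else {
    spectral_embed(gg, method, d = as.integer(d))
  }
  seeds <- derive_seeds(seed, 2L)
  bic_trace <- NULL
  if (identical(K, "auto")) {
    sel <- select_k_bic(emb$X, K_range = K_range, seed = seeds[1L],
                        n_init = n_init)
    fit <- sel$best
    bic_trace <- sel$bic
  } else {
    fit <- fit_gmm(emb$X, as.integer(K), seed = seeds[1L], n_init = n_init)
  }
  cl <- assign_clusters(fit, emb$X)
  structure(list(clustering = cl,
                 diagnostics = list(method = method, d = emb$d, K = fit$K,
                                    d_hat = emb$d_hat %||% emb$d,
                                    eigenvalues = emb$eigenvalues,
                                    bic_trace = bic_trace, fit = fit,
                                    embedding = emb),
                 index_map = lcc$index_map),
            class = "tt_spectral_clustering")
}

#' @export
print.tt_spectral_clustering <- function(x, ...) {
  cat(sprintf("tt_spectral_clustering: %s, d = %d, K = %d\n",
              x$diagnostics$method, x$diagnostics$d, x$diagnostics$K))
  print(x$clustering)
  invisible(x)
}

#' Configuration for the two-truths Monte-Carlo experiment
#'
#' @param tt_params A [two_truths_params()] model.
#' @param n Vertices per sampled graph.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param d `"fixed"` embedding dimension `d_fixed`, or `"auto"`.
#' @param K `"fixed"` cluster count `K_fixed`, or `"auto"`.
#' @param d_fixed,K_fixed Values used in fixed mode (default 2 and 2).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param ari_threshold Recovery threshold on ARI (in `(0,1)`).
#' @param n_init Random GMM restarts per fit.
#' @return A list of class `tt_experiment_config`.
#' @export
experiment_config <- function(tt_params = default_two_truths_params(),
                              n = 4000, n_reps = 50,
                              d = c("fixed", "auto"), K = c("fixed", "auto"),
                              d_fixed = 2L, K_fixed = 2L, seed = 1L,
                              ari_threshold = 0.95, n_init = 5L) {
  d <- match.arg(d)
  K <- match.arg(K)
  stopifnot(inherits(tt_params, "tt_two_truths"), n_reps >= 1,
            ari_threshold > 0, ari_threshold < 1)
  structure(list(tt_params = tt_params, n = n, n_reps = as.integer(n_reps),
                 d_mode = d, K_mode = K, d_fixed = as.integer(d_fixed),
                 K_fixed = as.integer(K_fixed), seed = as.integer(seed),
                 ari_threshold = ari_threshold, n_init = as.integer(n_init)),
            class = "tt_experiment_config")
}

#' Monte-Carlo two-truths experiment
#'
#' Samples replicate graphs from a four-block two-truths SBM, runs
#' `GMM o LSE` and `GMM o ASE` on each (by default with `d = K = 2`), and
#' scores each clustering against both collapsed truths (hemisphere and
#' tissue) via the adjusted Rand index. The headline summary is the fraction
#' of replicates in which the Laplacian embedding recovers the hemisphere
#' bipartition and the adjacency embedding recovers the tissue bipartition
#' above the ARI threshold.
#'
#' @param cfg An [experiment_config()].
#' @param check_params If `TRUE`, first run [validate_two_truths()] on the
#'   model and warn when it fails (adds the cost of the Chernoff
#'   estimation).
#' @return An object of class `tt_experiment`: `results` (one row per
#'   successful replicate with the four ARIs, the per-method `d` and `K`,
#'   and the delta coordinates `x_rep`, `y_rep`), `summary` (recovery
#'   fractions, mean deltas, quadrant fractions), `failures`, `config`.
#' @export
two_truths_experiment <- function(cfg, check_params = FALSE) {
  stopifnot(inherits(cfg, "tt_experiment_config"))
  if (check_params) {
    v <- validate_two_truths(cfg$tt_params, seed = cfg$seed)
    if (!v$pass) warning("model fails the two-truths validation report")
  }
  seeds <- derive_seeds(cfg$seed, 2L * cfg$n_reps)
  rows <- list()
  failures <- 0L
  for (r in seq_len(cfg$n_reps)) {
    row <- tryCatch({
      g <- sample_sbm(cfg$tt_params, cfg$n, seed = seeds[2L * r - 1L])
      lcc <- largest_connected_component(g)
      gg <- lcc$graph
      hemi <- collapse_membership(gg, "hemisphere")
      tiss <- collapse_membership(gg, "tissue")
      out <- list(rep = r, seed = seeds[2L * r - 1L])
      for (m in c("LSE", "ASE")) {
        emb <- if (cfg$d_mode == "auto") embed_auto(gg, m) else {
          spectral_embed(gg, m, d = cfg$d_fixed)
        }
        fit <- if (cfg$K_mode == "auto") {
          select_k_bic(emb$X, seed = seeds[2L * r], n_init = cfg$n_init)$best
        } else {
          fit_gmm(emb$X, cfg$K_fixed, seed = seeds[2L * r],
                  n_init = cfg$n_init)
        }
        cl <- assign_clusters(fit, emb$X)
        out[[paste0("ari_", tolower(m), "_hemisphere")]] <- ari(cl, hemi)
        out[[paste0("ari_", tolower(m), "_tissue")]] <- ari(cl, tiss)
        out[[paste0("d_", tolower(m))]] <- emb$d
        out[[paste0("k_", tolower(m))]] <- fit$K
      }
      out$x_rep <- out$ari_lse_hemisphere - out$ari_lse_tissue
      out$y_rep <- out$ari_ase_hemisphere - out$ari_ase_tissue
      as.data.frame(out)
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(row)) failures <- failures + 1L else {
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop("all replicates failed", call. = FALSE)
  results <- do.call(rbind, rows)
  thr <- cfg$ari_threshold
  summary <- list(
    n_reps = cfg$n_reps, n_ok = nrow(results), failures = failures,
    frac_lse_hemisphere = mean(results$ari_lse_hemisphere > thr),
    frac_ase_tissue = mean(results$ari_ase_tissue > thr),
    mean_x = mean(results$x_rep), mean_y = mean(results$y_rep),
    quadrants = quadrant_fractions(results$x_rep, results$y_rep))
  structure(list(results = results, summary = summary, config = cfg),
            class = "tt_experiment")
}

quadrant_fractions <- function(x, y) {
  c(`+-` = mean(x > 0 & y < 0), `++` = mean(x > 0 & y > 0),
    `-+` = mean(x < 0 & y > 0), `--` = mean(x < 0 & y < 0),
    origin = mean(x == 0 & y == 0))
}

#' @export
print.tt_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("tt_experiment: %d/%d replicates ok (n = %d, %s/%s)\n",
              s$n_ok, s$n_reps, x$config$n, x$config$d_mode,
              x$config$K_mode))
  cat(sprintf("P(ARI(LSE, hemisphere) > %.2f) = %.3f\n",
              x$config$ari_threshold, s$frac_lse_hemisphere))
  cat(sprintf("P(ARI(ASE, tissue)     > %.2f) = %.3f\n",
              x$config$ari_threshold, s$frac_ase_tissue))
  cat("quadrant fractions (x = LSE delta, y = ASE delta):\n")
  print(round(s$quadrants, 3))
  invisible(x)
}

#' Delta-ARI summary of an experiment
#'
#' Per-replicate differences `x = ARI(LSE, hemisphere) - ARI(LSE, tissue)`
#' and `y = ARI(ASE, hemisphere) - ARI(ASE, tissue)`. A replicate in the
#' `(+,-)` quadrant means the Laplacian embedding identified the hemisphere
#' truth better while the adjacency embedding identified the tissue truth
#' better.
#'
#' @param experiment A [two_truths_experiment()] result (or its `results`
#'   data frame).
#' @return A list of class `tt_delta_ari`: `table` (rep, x, y), `quadrants`,
#'   `mean_x`, `mean_y`.
#' @export
delta_ari_summary <- function(experiment) {
  res <- if (inherits(experiment, "tt_experiment")) experiment$results else {
    experiment
  }
  if (!nrow(res)) stop("empty results", call. = FALSE)
  tab <- data.frame(rep = res$rep, x = res$x_rep, y = res$y_rep)
  structure(list(table = tab,
                 quadrants = quadrant_fractions(tab$x, tab$y),
                 mean_x = mean(tab$x), mean_y = mean(tab$y)),
            class = "tt_delta_ari")
}

#' @export
print.tt_delta_ari <- function(x, ...) {
  cat(sprintf("tt_delta_ari: %d replicates, mean (x, y) = (%.3f, %.3f)\n",
              nrow(x$table), x$mean_x, x$mean_y))
  print(round(x$quadrants, 3))
  invisible(x)
}

#' A priori two-block projection coordinates for a set of labeled graphs
#'
#' For each graph and each binary label track, projects the graph onto the
#' two-block SBM given by that track, and maps the observed
#' `B = [a, b; b, c]` to the `(x, y)` coordinates of [two_block_coords()]
#' together with the [classify_structure()] class. Two points per graph: the
#' hemisphere projection (expected in the affinity region) and the tissue
#' projection (expected in the core-periphery region).
#'
#' @param gs List of [tt_graph()]s carrying hemisphere and tissue tracks.
#' @param margin Dominance margin for classification.
#' @return A data frame with columns `graph`, `track`, `a`, `b`, `c`, `x`,
#'   `y`, `class`.
#' @export
eda_projection_points <- function(gs, margin = 2) {
  if (inherits(gs, "tt_graph")) gs <- list(gs)
  rows <- list()
  for (i in seq_along(gs)) {
    for (track in c("hemisphere", "tissue")) {
      membership <- collapse_membership(gs[[i]], track)
      proj <- project_to_blocks(gs[[i]], membership)
      a <- proj$B_hat[1L, 1L]
      b <- proj$B_hat[1L, 2L]
      c_ <- proj$B_hat[2L, 2L]
      if (anyNA(c(a, b, c_))) {
        warning("graph ", i, " track ", track,
                ": block too small, point skipped")
        next
      }
      co <- two_block_coords(a, b, c_)
      rows[[length(rows) + 1L]] <- data.frame(
        graph = i, track = track, a = a, b = b, c = c_, x = co$x, y = co$y,
        class = classify_structure(a, b, c_, margin = margin),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Chernoff-ratio map over two-block SBM space
#'
#' Evaluates the Chernoff ratio on a grid of two-block models parameterized
#' by the scale-free coordinates `(x, y)`: each cell corresponds to
#' `B = [s, s y; s y, s x]` (so `max(a, c) = s`, `min(a, c) = s x`,
#' `b = s y`), with fixed block probabilities. The `rho = 1` level set,
#' extracted by linear interpolation along grid rows and columns, separates
#' the region where adjacency embedding is preferred from the region where
#' Laplacian embedding is preferred; the diagonal `y = x` is the rank-1
#' submodel boundary.
#'
#' @param resolution Grid points per axis (grid covers `(0, 1]^2`).
#' @param s Density scale `max(a, c)`; the ratio is not scale-free, so the
#'   map is drawn at a fixed scale.
#' @param pi2 Two-block membership probabilities.
#' @param n Graph size for the empirical limit parameters.
#' @param n_graphs Replicates per cell.
#' @param seed Integer seed.
#' @return An object of class `tt_map`: `grid` (data frame `x`, `y`, `a`,
#'   `b`, `c`, `rho`), `contour` (interpolated `rho = 1` points), and the
#'   map parameters.
#' @export
chernoff_map <- function(resolution = 26L, s = 0.1, pi2 = c(0.5, 0.5),
                         n = 1000, n_graphs = 2, seed = 1L) {
  if (resolution < 5L) stop("resolution must be >= 5", call. = FALSE)
  if (s <= 0 || s > 1) stop("s must be in (0, 1]", call. = FALSE)
  xs <- seq_len(resolution) / resolution
  ys <- xs
  cells <- expand.grid(x = xs, y = ys)
  seeds <- derive_seeds(seed, nrow(cells))
  rho <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    B <- matrix(c(s, s * cells$y[i], s * cells$y[i], s * cells$x[i]), 2L, 2L)
    rho[i] <- tryCatch(
      chernoff_ratio_sbm(sbm_params(pi2, B), d = 2L, n = n,
                         n_graphs = n_graphs, seed = seeds[i])$rho,
      error = function(e) NA_real_)
  }
  grid <- data.frame(x = cells$x, y = cells$y, a = s, b = s * cells$y,
                     c = s * cells$x, rho = rho)
  structure(list(grid = grid, contour = rho_unit_contour(grid),
                 resolution = resolution, s = s, pi2 = pi2, n = n,
                 n_graphs = n_graphs, seed = seed,
                 rank1_curve = "y = x"),
            class = "tt_map")
}

# rho = 1 level set by linear interpolation in log(rho) along grid lines
rho_unit_contour <- function(grid) {
  pts <- list()
  interp <- function(v1, v2, r1, r2) {
    w <- log(r1) / (log(r1) - log(r2))
    v1 + w * (v2 - v1)
  }
  scan_line <- function(df, along) {
    df <- df[order(df[[along]]), ]
    lr <- log(df$rho)
    for (i in seq_len(nrow(df) - 1L)) {
      if (is.na(lr[i]) || is.na(lr[i + 1L])) next
      if (lr[i] == 0) {
        pts[[length(pts) + 1L]] <<- df[i, c("x", "y")]
      } else if (lr[i] * lr[i + 1L] < 0) {
        p <- df[i, c("x", "y")]
        p[[along]] <- interp(df[[along]][i], df[[along]][i + 1L],
                             df$rho[i], df$rho[i + 1L])
        pts[[length(pts) + 1L]] <<- p
      }
    }
  }
  for (yv in unique(grid$y)) scan_line(grid[grid$y == yv, ], "x")
  for (xv in unique(grid$x)) scan_line(grid[grid$x == xv, ], "y")
  if (!length(pts)) return(data.frame(x = numeric(0), y = numeric(0)))
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  out
}

#' @export
print.tt_map <- function(x, ...) {
  cat(sprintf("tt_map: %dx%d grid at scale s = %g (n = %d)\n",
              x$resolution, x$resolution, x$s, x$n))
  cat(sprintf("rho range: [%.3f, %.3f]; %d contour points on rho = 1\n",
              min(x$grid$rho, na.rm = TRUE), max(x$grid$rho, na.rm = TRUE),
              nrow(x$contour)))
  invisible(x)
}
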