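#' Standardized z-score against a null ensemble
#'
#' \deqn{z = \frac{X_{obs} - \bar{X}}{Sd_X}}
#' with \eqn{\bar{X}} and \eqn{Sd_X} the mean and standard deviation of the
#' simulated metric values. Values with `|z| > 2` are considered
#' significant, and the ecological reading depends on the metric and the
#' sign of the deviation: WNODA (nested / anti-nested), same-module WNODA
#' (nested / anti-nested), modularity (modular / anti-modular), FDis
#' (limiting similarity when high, niche filtering when low), CWM (trait
#' matching when high, trait barrier when low).
#'
#' @param x_obs Observed metric value.
#' @param null_values Numeric vector of the metric over null replicates
#'   (length >= 2, positive spread).
#' @param metric One of `"wnoda"`, `"wnoda_sm"`, `"modularity"`, `"fdis"`,
#'   `"cwm"`.
#' @return A `zscore_result` tibble row: `metric`, `x_obs`, `null_mean`,
#'   `null_sd`, `z`, `n_reps`, `interpretation`.
#' @export
zscore <- function(x_obs, null_values,
                   metric = c("wnoda", "wnoda_sm", "modularity", "fdis", "cwm")) {
  metric <- match.arg(metric)
  null_values <- null_values[is.finite(null_values)]
  if (length(null_values) < 2) abort("Need at least two finite null values.")
  s <- sd(null_values)
  if (s == 0) abort("Degenerate null ensemble: standard deviation is 0.")
  z <- (x_obs - mean(null_values)) / s
  out <- tibble::tibble(
    metric = metric, x_obs = x_obs, null_mean = mean(null_values),
    null_sd = s, z = z, n_reps = length(null_values),
    interpretation = interpret_z(metric, z)
  )
  class(out) <- c("zscore_result", class(out))
  out
}

interpret_z <- function(metric, z) {
  if (!is.finite(z) || abs(z) <= 2) return("non-significant")
  high <- z > 2
  switch(metric,
    wnoda = if (high) "nested" else "anti-nested",
    wnoda_sm = if (high) "nested" else "anti-nested",
    modularity = if (high) "modular" else "anti-modular",
    fdis = if (high) "limiting similarity" else "niche filtering",
    cwm = if (high) "trait matching" else "trait barrier"
  )
}

#' Modularity z-score against the connectance-preserving null
#'
#' Runs module detection on the observed matrix (with the full restart
#' budget) and on each null replicate (with a reduced restart count, a
#' documented tractability knob), and standardizes the observed modularity
#' against the null distribution.
#'
#' @inheritParams find_modules
#' @param n_null Number of null replicates.
#' @param restarts_null Optimizer restarts per null replicate.
#' @param partition Optionally, a precomputed observed [module_partition()].
#' @param method_null Optimization method for null replicates.
#' @return List: `partition` (observed), `z` (a [zscore()] result),
#'   `null_values`.
#' @export
q_zscore <- function(m, objective = c("bipartite", "directed"),
                     n_null = 100, n_restarts = 100, restarts_null = 20,
                     seed = 1, partition = NULL,
                     method = "simulated_annealing",
                     method_null = "simulated_annealing") {
  objective <- match.arg(objective)
  if (is.null(partition)) {
    partition <- find_modules(m, objective, n_restarts = n_restarts,
                              seed = seed, method = method)
  }
  ens <- build_ensemble("vaznull", m, n = n_null, base_seed = offset_seed(seed, 1))
  null_seeds <- derive_seeds(offset_seed(seed, 2), n_null)
  null_q <- purrr::map2_dbl(ens$replicates, null_seeds, function(rep, s) {
    find_modules(rep, objective, n_restarts = restarts_null, seed = s,
                 method = method_null)$q
  })
  list(partition = partition,
       z = zscore(partition$q, null_q, "modularity"),
       null_values = null_q)
}

#' Nestedness z-scores
#'
#' `wnoda_zscore()` standardizes whole-matrix WNODA against the
#' connectance-preserving (Vazquez-style) null. `wnoda_sm_zscore()`
#' standardizes same-module WNODA and each module's internal WNODA against
#' the module-membership-constrained null, which randomizes interactions
#' only within module blocks.
#'
#' @inheritParams q_zscore
#' @param p A [module_partition()] (for the module-constrained versions).
#' @return `wnoda_zscore()`: list `z`, `null_values`. `wnoda_sm_zscore()`:
#'   list `z` (same-module WNODA), `per_module` (tibble of per-module
#'   z-scores; modules with <= 1 consumer are `NA`), `null_values`.
#' @export
wnoda_zscore <- function(m, n_null = 1000, seed = 1) {
  obs <- wnoda(m)
  ens <- build_ensemble("vaznull", m, n = n_null, base_seed = offset_seed(seed, 3))
  null_w <- purrr::map_dbl(ens$replicates, wnoda)
  list(z = zscore(obs, null_w, "wnoda"), null_values = null_w)
}

#' @rdname wnoda_zscore
#' @export
wnoda_sm_zscore <- function(m, p, n_null = 1000, seed = 1) {
  obs <- wnoda_sm(m, p)
  ens <- build_ensemble("module_constrained", m, p = p, n = n_null,
                        base_seed = offset_seed(seed, 4))
  null_sm <- purrr::map_dbl(ens$replicates, ~ wnoda_sm(.x, p)$wnoda_sm)
  mods <- sort(unique(p$assignment$module))
  per_module <- purrr::map_dfr(mods, function(s) {
    o <- module_wnoda(m, p, s)
    if (is.na(o)) {
      return(tibble::tibble(module = s, wnoda = NA_real_, z = NA_real_,
                            interpretation = NA_character_))
    }
    nulls <- purrr::map_dbl(ens$replicates, ~ module_wnoda(.x, p, s))
    zr <- zscore(o, nulls, "wnoda_sm")
    tibble::tibble(module = s, wnoda = o, z = zr$z, interpretation = zr$interpretation)
  })
  list(z = zscore(obs$wnoda_sm, null_sm, "wnoda_sm"),
       per_module = per_module, null_values = null_sm)
}

#' Module assembly tests: FDis, CWM and composition
#'
#' For every module, compares observed functional dispersion and
#' community-weighted trait means of the consumers exploiting the module's
#' resources against Monte Carlo null modules built by resampling
#' interaction events from the whole network while keeping the number of
#' events per module fixed. Categorical consumer traits and the habitat or
#' prey-category composition of the module's resources are tested with
#' chi-square contingency tests against whole-network proportions.
#'
#' @inheritParams module_fdis
#' @param t A [trait_table()] covering the consumers of `m`.
#' @param n_null Null modules per empirical module (2000 in the reference
#'   design).
#' @param seed Integer seed.
#' @param resource_meta Optional [node_metadata()] tibble for the resource
#'   side (habitat per community, or prey category per prey item).
#' @param trait_weighting `"species"` (each module consumer counts once in
#'   categorical tables; default) or `"abundance"`.
#' @param abundance Named consumer abundances (for
#'   `trait_weighting = "abundance"`).
#' @return A list with `fdis` (tibble per module), `cwm` (tibble per module
#'   x quantitative trait), `trait_chisq`, `composition_chisq`.
#' @export
module_assembly <- function(m, p, t, n_null = 2000, seed = 1,
                            resource_meta = NULL,
                            trait_weighting = c("species", "abundance"),
                            abundance = NULL) {
  trait_weighting <- match.arg(trait_weighting)
  stopifnot(inherits(t, "trait_table"))
  space <- gower_space(t)
  v <- partition_vectors(m, p)
  a <- unclass(m)
  types <- attr(t, "trait_types")
  quant <- names(types)[types == "quantitative"]
  cats <- names(types)[types == "categorical"]
  trait_vals <- lapply(quant, function(nm) setNames(t[[nm]], t$consumer))
  names(trait_vals) <- quant
  mods <- sort(unique(c(v$zr, v$zc)))

  fdis_rows <- list()
  cwm_rows <- list()
  trait_chisq_rows <- list()
  comp_rows <- list()

  for (s in mods) {
    rows <- which(v$zr == s)
    if (length(rows) == 0) next
    n_events <- sum(a[rows, , drop = FALSE])
    obs <- module_fdis(m, p, s, space)
    obs_cwm <- vapply(quant, function(nm) {
      cwm(trait_vals[[nm]][obs$consumers$consumer], setNames(obs$consumers$weight, obs$consumers$consumer))
    }, numeric(1))

    ens <- build_ensemble("module_resample", m, n = n_null,
                          base_seed = offset_seed(seed, 10 + s),
                          n_events = n_events)
    null_fdis <- purrr::map_dbl(ens$replicates, resampled_fdis, space = space)
    z_f <- zscore(obs$fdis, null_fdis, "fdis")
    fdis_rows[[length(fdis_rows) + 1]] <- tibble::tibble(
      module = s, fdis = obs$fdis, null_mean = z_f$null_mean,
      null_sd = z_f$null_sd, z = z_f$z, interpretation = z_f$interpretation
    )
    for (nm in quant) {
      null_c <- purrr::map_dbl(ens$replicates, resampled_cwm,
                               trait_values = trait_vals[[nm]])
      z_c <- zscore(obs_cwm[[nm]], null_c, "cwm")
      cwm_rows[[length(cwm_rows) + 1]] <- tibble::tibble(
        module = s, trait = nm, cwm = obs_cwm[[nm]], null_mean = z_c$null_mean,
        null_sd = z_c$null_sd, z = z_c$z, interpretation = z_c$interpretation
      )
    }

    members <- p$assignment$node[p$assignment$side == "cols" & p$assignment$module == s]
    if (length(members) > 0 && length(cats) > 0) {
      for (nm in cats) {
        lv <- sort(unique(t[[nm]]))
        expected <- category_proportions(t[[nm]], t$consumer, lv, trait_weighting, abundance)
        obs_counts <- category_counts(t[[nm]][match(members, t$consumer)], members, lv,
                                      trait_weighting, abundance)
        if (sum(obs_counts) > 0 && length(lv) > 1) {
          res <- categorical_composition_test(obs_counts, expected)
          trait_chisq_rows[[length(trait_chisq_rows) + 1]] <- tibble::tibble(
            module = s, trait = nm, statistic = res$statistic, df = res$df,
            p_value = res$p_value
          )
        }
      }
    }

    if (!is.null(resource_meta)) {
      cat_of <- setNames(resource_meta$category, resource_meta$node)
      lv <- sort(unique(resource_meta$category))
      all_w <- tapply(rowSums(a), cat_of[rownames(a)], sum)
      expected <- setNames(rep(0, length(lv)), lv)
      expected[names(all_w)] <- all_w / sum(all_w)
      mod_w <- tapply(rowSums(a[rows, , drop = FALSE]), cat_of[rownames(a)[rows]], sum)
      obs_counts <- setNames(rep(0, length(lv)), lv)
      obs_counts[names(mod_w)] <- mod_w
      res <- categorical_composition_test(obs_counts, expected)
      comp_rows[[length(comp_rows) + 1]] <- tibble::tibble(
        module = s, statistic = res$statistic, df = res$df, p_value = res$p_value
      )
    }
  }

  list(
    fdis = dplyr::bind_rows(fdis_rows),
    cwm = dplyr::bind_rows(cwm_rows),
    trait_chisq = dplyr::bind_rows(trait_chisq_rows),
    composition_chisq = dplyr::bind_rows(comp_rows)
  )
}

category_proportions <- function(values, consumers, levels, weighting, abundance) {
  w <- if (weighting == "abundance") {
    if (is.null(abundance)) abort("Abundance weighting needs `abundance`.")
    abundance[consumers]
  } else rep(1, length(consumers))
  tot <- tapply(w, factor(values, levels = levels), sum, default = 0)
  setNames(as.numeric(tot) / sum(tot), levels)
}

category_counts <- function(values, consumers, levels, weighting, abundance) {
  w <- if (weighting == "abundance") abundance[consumers] else rep(1, length(consumers))
  cnt <- tapply(w, factor(values, levels = levels), sum, default = 0)
  setNames(as.numeric(cnt), levels)
}

#' Abundance-degree regression
#'
#' Ordinary least squares of node degree on log10 abundance, testing the
#' abundance-based (neutral) assembly signal: more abundant consumers are
#' expected to occupy more communities and consume more prey types.
#'
#' @param data Data frame with columns `abundance` (positive counts) and
#'   `degree` (non-negative integers), one row per consumer.
#' @return A `regression_result` tibble: `r_squared`, `f_statistic`,
#'   `p_value`, `n_points`, `slope`, `intercept`.
#' @export
abundance_degree_regression <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("abundance", "degree") %in% names(data))) {
    abort("Need columns `abundance` and `degree`.")
  }
  if (nrow(data) < 3) abort("Need at least 3 consumers.")
  if (any(data$abundance <= 0)) abort("Abundances must be positive.")
  x <- log10(data$abundance)
  if (sd(x) == 0) abort("Zero variance in log10(abundance).")
  fit <- lm(data$degree ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  out <- tibble::tibble(
    r_squared = sm$r.squared,
    f_statistic = unname(fstat[1]),
    p_value = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    n_points = nrow(data),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1])
  )
  class(out) <- c("regression_result", class(out))
  out
}

offset_seed <- function(seed, k) (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L

#' Run the full structural analysis
#'
#' Orchestrates the whole pipeline for one or two networks: module
#' detection with restart policy, normalized modularity, modularity and
#' nestedness z-scores against the connectance-preserving and
#' module-constrained nulls, per-module WNODA, FDis and CWM against
#' Monte Carlo null modules, composition chi-square tests, and the
#' abundance-degree regression. All randomness derives from `config$seed`,
#' so reruns with the same config are bit-identical.
#'
#' @param config A list with entries:
#'   \describe{
#'     \item{networks}{Named list of [weighted_matrix()] objects (e.g.
#'       `occurrence`, `foodweb`).}
#'     \item{objectives}{Named character: `"bipartite"` or `"directed"` per
#'       network (defaults: occurrence bipartite, foodweb directed).}
#'     \item{traits}{A [trait_table()].}
#'     \item{abundance}{Named per-consumer abundances.}
#'     \item{resource_meta}{Named list of [node_metadata()] tibbles per
#'       network (habitat / prey categories); optional.}
#'     \item{seed}{Integer master seed.}
#'     \item{n_null_network, n_null_module, n_restarts, restarts_null}{Replicate
#'       and restart counts (defaults 100, 500, 100, 20).}
#'     \item{method_null}{Optimization method for null-replicate module
#'       detection; `"weighted_label_propagation"` is much faster at equal
#'       attained modularity on null-scale matrices.}
#'   }
#' @return A `network_analysis` object: per-network results plus the config
#'   echo (seeds and replicate counts logged).
#' @export
run_full_analysis <- function(config) {
  needed <- c("networks", "traits", "abundance", "seed")
  missing <- setdiff(needed, names(config))
  if (length(missing) > 0) {
    abort(paste0("Config missing entries: ", paste(missing, collapse = ", ")))
  }
  defaults <- list(n_null_network = 100, n_null_module = 500,
                   n_restarts = 100, restarts_null = 20,
                   method_null = "simulated_annealing")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  objectives <- config$objectives
  results <- list()
  for (nm in names(config$networks)) {
    m <- config$networks[[nm]]
    objective <- if (!is.null(objectives[[nm]])) objectives[[nm]]
      else if (identical(attr(m, "kind"), "foodweb")) "directed" else "bipartite"
    seed_net <- offset_seed(config$seed, match(nm, names(config$networks)) * 100)
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        abort(sprintf("Stage '%s' failed for network '%s': %s", what, nm,
                      conditionMessage(e)))
      })
    }
    qz <- stage("modularity", q_zscore(
      m, objective, n_null = config$n_null_network,
      n_restarts = config$n_restarts, restarts_null = config$restarts_null,
      method_null = config$method_null, seed = seed_net))
    part <- qz$partition
    q_norm <- stage("normalization", normalize_q(m, part))
    wz <- stage("nestedness", wnoda_zscore(m, n_null = config$n_null_network,
                                           seed = seed_net))
    smz <- stage("nestedness_sm", wnoda_sm_zscore(m, part,
                                                  n_null = config$n_null_network,
                                                  seed = seed_net))
    assembly <- stage("assembly", module_assembly(
      m, part, config$traits, n_null = config$n_null_module, seed = seed_net,
      resource_meta = config$resource_meta[[nm]]))
    reg <- stage("regression", abundance_degree_regression(
      dplyr::inner_join(node_degree(m, "cols"),
                        tibble::tibble(node = names(config$abundance),
                                       abundance = as.numeric(config$abundance)),
                        by = "node")))
    results[[nm]] <- list(
      partition = part,
      q = part$q,
      q_normalized = q_norm,
      n_modules = part$n_modules,
      q_z = qz$z,
      wnoda_z = wz$z,
      wnoda_sm_z = smz$z,
      module_nestedness = smz$per_module,
      assembly = assembly,
      regression = reg,
      seed = seed_net
    )
  }
  structure(list(networks = results,
                 config = config[c("seed", "n_null_network", "n_null_module",
                                   "n_restarts", "restarts_null")]),
            class = "network_analysis")
}

#' @export
print.network_analysis <- function(x, ...) {
  cat("<network_analysis>\n")
  for (nm in names(x$networks)) {
    r <- x$networks[[nm]]
    cat(sprintf(
      "  %s: Q = %.3f (norm %.3f), %d modules, ZQ = %.2f; WNODA z = %.2f, WNODA-SM z = %.2f; degree~log10(abundance) R2 = %.2f\n",
      nm, r$q, r$q_normalized, r$n_modules, r$q_z$z, r$wnoda_z$z, r$wnoda_sm_z$z,
      r$regression$r_squared))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.network_analysis <- function(x, ...) {
  purrr::map_dfr(names(x$networks), function(nm) {
    r <- x$networks[[nm]]
    tibble::tibble(
      network = nm, q = r$q, q_normalized = r$q_normalized,
      n_modules = r$n_modules, q_z = r$q_z$z, wnoda_z = r$wnoda_z$z,
      wnoda_sm_z = r$wnoda_sm_z$z, regression_r2 = r$regression$r_squared,
      regression_f = r$regression$f_statistic, regression_p = r$regression$p_value
    )
  })
}

#' @exportS3Method generics::tidy
tidy.network_analysis <- function(x, ...) {
  purrr::map_dfr(names(x$networks), function(nm) {
    r <- x$networks[[nm]]
    dplyr::bind_rows(
      dplyr::mutate(r$q_z, network = nm, level = "network", module = NA_integer_,
                    trait = NA_character_),
      dplyr::mutate(r$wnoda_z, network = nm, level = "network", module = NA_integer_,
                    trait = NA_character_),
      dplyr::mutate(r$wnoda_sm_z, network = nm, level = "network", module = NA_integer_,
                    trait = NA_character_),
      dplyr::transmute(r$module_nestedness[!is.na(r$module_nestedness$z), ],
                       metric = "wnoda_sm", x_obs = .data$wnoda, z = .data$z,
                       interpretation = .data$interpretation, network = nm,
                       level = "module", module = .data$module, trait = NA_character_),
      dplyr::transmute(r$assembly$fdis, metric = "fdis", x_obs = .data$fdis,
                       null_mean = .data$null_mean, null_sd = .data$null_sd,
                       z = .data$z, interpretation = .data$interpretation,
                       network = nm, level = "module", module = .data$module,
                       trait = NA_character_),
      dplyr::transmute(r$assembly$cwm, metric = "cwm", x_obs = .data$cwm,
                       null_mean = .data$null_mean, null_sd = .data$null_sd,
                       z = .data$z, interpretation = .data$interpretation,
                       network = nm, level = "module", module = .data$module,
                       trait = .data$trait)
    )
  })
}
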