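#' Averaged life-history Z index
#'
#' Each life-history trait (body length, body mass, longevity) is transformed
#' to a Z score, `Z_i = (x_i - mean) / sd`, over the species with a
#' non-missing value; each species' index is the mean of its available Z
#' scores, so species with partial trait coverage still receive an index.
#' Constant or all-missing columns are excluded with a warning.
#'
#' @param traits data.frame of trait columns (rows = species).
#' @param columns trait columns to use.
#' @return list with `z` (matrix of Z scores), `index` (named vector, `NA`
#'   when no trait is available), `n_traits` (per-species count).
#' @export
zscore_index <- function(traits, columns = c("body_length", "body_mass",
                                             "longevity")) {
  columns <- intersect(columns, names(traits))
  if (length(columns) == 0) stop("no trait columns found")
  z <- sapply(columns, function(cn) {
    x <- traits[[cn]]
    if (sum(!is.na(x)) < 2 || stats::sd(x, na.rm = TRUE) == 0) {
      warning("trait column excluded (constant or all missing): ", cn)
      return(rep(NA_real_, length(x)))
    }
    (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  })
  rownames(z) <- if (!is.null(traits$species)) traits$species
                 else rownames(traits)
  n_traits <- rowSums(!is.na(z))
  index <- rowMeans(z, na.rm = TRUE)
  index[n_traits == 0] <- NA_real_
  list(z = z, index = index, n_traits = n_traits)
}

#' Assemble per-species analysis records from a synthetic (or loaded) study
#'
#' Joins the trait table with every species' breeding-window climate summary
#' ([summarize_species()]) and the life-history index, giving the flat table
#' the regressions run on.
#'
#' @param study a `synthetic_study` (or equivalent list with `tree`,
#'   `traits`, `grid`, `masks`).
#' @return data.frame, one row per species, rownames = species.
#' @export
assemble_records <- function(study) {
  traits <- study$traits
  sums <- do.call(rbind, lapply(seq_len(nrow(traits)), function(i) {
    w <- breeding_window(traits$breed_start[i], traits$breed_end[i])
    summarize_species(study$grid, study$masks[[traits$species[i]]], w)
  }))
  rec <- cbind(traits, sums)
  idx <- zscore_index(rec)
  rec$lh_index <- as.numeric(idx$index[rec$species])
  rownames(rec) <- rec$species
  rec
}

.climate_vars <- c("temp_median_breeding", "temp_seasonality_breeding",
                   "temp_interannual_breeding", "precip_median_breeding",
                   "precip_seasonality_breeding",
                   "precip_interannual_breeding")

#' Run the core comparative models
#'
#' For each breeding-season climate variable, fits the OU-PGLS
#' `climate ~ sds`, with and without range-area weights and with and without
#' viviparous species; runs the phylogeny-corrected variance-heterogeneity
#' contrast for temperature and precipitation medians; the ANCOVA
#' `temperature ~ sds * breeding length`; the reproductive-mode model
#' `temperature ~ sds * reproductive mode`; the phylogenetic logistic
#' regression `sds ~ ambient temperature` as robustness check; and Pagel's
#' lambda signal for the eight study variables.
#'
#' @param records output of [assemble_records()].
#' @param tree a `phylo` object.
#' @param weighted also run area-weighted fits.
#' @param dist optional precomputed patristic distance matrix.
#' @return list with `pgls` (tidy data.frame), `variance_tests`, `ancova`,
#'   `repro_model`, `logistic`, `lambda_signal`, `exclusions`.
#' @export
run_core_models <- function(records, tree, weighted = TRUE, dist = NULL) {
  if (is.null(dist)) dist <- ape::cophenetic.phylo(tree)
  w_all <- area_weights(records[tree$tip.label, "range_area"])
  names(w_all) <- tree$tip.label
  subsets <- list(all = tree$tip.label,
                  oviparous = rownames(records)[records$reproductive_mode == 0])
  weight_opts <- if (weighted) c(FALSE, TRUE) else FALSE

  pgls_rows <- list()
  for (sub in names(subsets)) {
    keep <- subsets[[sub]]
    tr <- if (length(keep) < length(tree$tip.label))
      ape::drop.tip(tree, setdiff(tree$tip.label, keep)) else tree
    dsub <- dist[tr$tip.label, tr$tip.label]
    rec <- records[tr$tip.label, ]
    for (uw in weight_opts) {
      w <- if (uw) area_weights(rec$range_area) else NULL
      if (!is.null(w)) names(w) <- rownames(rec)
      for (v in .climate_vars) {
        dat <- data.frame(y = rec[[v]], sds = rec$sds, row.names = rownames(rec))
        fit <- pgls_fit(y ~ sds, dat, tr, correlation = "OU", dist = dsub,
                        weights = w)
        pgls_rows[[length(pgls_rows) + 1]] <- data.frame(
          variable = v, subset = sub, weighted = uw,
          slope = unname(fit$coefficients["sds"]),
          p = unname(fit$pval["sds"]), alpha = fit$alpha, n = fit$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  pgls_tab <- do.call(rbind, pgls_rows)

  var_tests <- lapply(c(temp = "temp_median_breeding",
                        precip = "precip_median_breeding"), function(v) {
    variance_heterogeneity_test(
      stats::setNames(records[tree$tip.label, v], tree$tip.label),
      records[tree$tip.label, "sds"], tree, dist = dist)
  })

  rec_all <- records[tree$tip.label, ]
  ancova <- ancova_interaction(
    stats::setNames(rec_all$temp_median_breeding, tree$tip.label),
    rec_all$sds, rec_all$window_length, tree, dist = dist)

  # viviparity is nearly confined to GSD, so the interaction column can be
  # empty; drop inestimable terms instead of failing
  repro_dat <- data.frame(y = rec_all$temp_median_breeding, sds = rec_all$sds,
                          repro = rec_all$reproductive_mode,
                          row.names = tree$tip.label)
  repro_model <- NULL
  for (f in list(y ~ sds * repro, y ~ sds + repro, y ~ sds)) {
    Xr <- stats::model.matrix(f, repro_dat)
    if (qr(Xr)$rank == ncol(Xr)) {
      repro_model <- pgls_fit(f, repro_dat, tree, correlation = "OU",
                              dist = dist)
      break
    }
  }

  logi_dat <- data.frame(sds = rec_all$sds,
                         temp = as.numeric(scale(rec_all$temp_median_breeding)),
                         row.names = tree$tip.label)
  logistic <- phylo_logistic_fit(sds ~ temp, logi_dat, tree, dist = dist)

  sig_vars <- c("sds", "reproductive_mode", .climate_vars)
  lambda_signal <- lapply(stats::setNames(sig_vars, sig_vars), function(v) {
    x <- stats::setNames(rec_all[[v]], tree$tip.label)
    if (stats::sd(x) == 0)  # constant trait: signal undefined
      return(structure(list(lambda = NA_real_, p = NA_real_),
                       class = "lambda_fit"))
    phylosig_lambda(x, tree)
  })

  list(pgls = pgls_tab, variance_tests = var_tests, ancova = ancova,
       repro_model = repro_model, logistic = logistic,
       lambda_signal = lambda_signal,
       exclusions = setdiff(records$species, tree$tip.label))
}

#' Group-wise test of ambient temperature against a reference value
#'
#' For each group (e.g. SDS x short/long breeding season), a one-sample
#' Wilcoxon signed-rank test of the temperatures against the reference (25
#' degrees C by default, the shared optimum suggested by the data), with
#' Benjamini-Hochberg correction across groups. Groups with fewer than 3
#' species are skipped with a flag.
#'
#' @param values numeric vector (temperatures).
#' @param groups group labels, same length.
#' @param reference reference temperature (default 25).
#' @return data.frame: group, n, median, p, p_adj, skipped.
#' @export
reference_temp_test <- function(values, groups, reference = 25) {
  groups <- factor(groups)
  rows <- lapply(levels(groups), function(g) {
    v <- values[groups == g & !is.na(values)]
    if (length(v) < 3)
      return(data.frame(group = g, n = length(v), median = stats::median(v),
                        p = NA_real_, skipped = TRUE))
    p <- stats::wilcox.test(v, mu = reference, exact = FALSE)$p.value
    data.frame(group = g, n = length(v), median = stats::median(v), p = p,
               skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !out$skipped
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out
}

#' Leave-one-continent-out robustness check
#'
#' Refits `formula` once per continent with that continent's species removed
#' (tree pruned to match); removals leaving fewer than `min_n` species are
#' flagged but still run.
#'
#' @param records output of [assemble_records()].
#' @param tree a `phylo` object.
#' @param formula PGLS formula over columns of `records`.
#' @param coef_name coefficient to report (default `"sds"`).
#' @param min_n flag threshold (default 10).
#' @param dist optional precomputed distances.
#' @return data.frame: continent_removed, n, estimate, p, alpha, flagged.
#' @export
continent_jackknife <- function(records, tree, formula, coef_name = "sds",
                                min_n = 10, dist = NULL) {
  conts <- unique(records$continent)
  if (length(conts) < 2) stop("need at least 2 continents")
  if (is.null(dist)) dist <- ape::cophenetic.phylo(tree)
  rows <- lapply(conts, function(ct) {
    keep <- rownames(records)[records$continent != ct]
    keep <- intersect(keep, tree$tip.label)
    tr <- if (length(keep) < length(tree$tip.label))
      ape::drop.tip(tree, setdiff(tree$tip.label, keep)) else tree
    fit <- pgls_fit(formula, records[tr$tip.label, ], tr, correlation = "OU",
                    dist = dist[tr$tip.label, tr$tip.label])
    data.frame(continent_removed = ct, n = fit$n,
               estimate = unname(fit$coefficients[coef_name]),
               p = unname(fit$pval[coef_name]), alpha = fit$alpha,
               flagged = fit$n < min_n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Draw `target` species keeping >= 1 representative per family: one per
# family first, the remainder uniform from the rest.
.family_subsample <- function(species, fam, target) {
  reps <- vapply(split(species, fam), function(s)
    s[sample.int(length(s), 1)], character(1))
  rest <- setdiff(species, reps)
  fill <- sample(rest, target - length(reps))
  c(unname(reps), fill)
}

#' Family-constrained subsampling robustness check
#'
#' Refits `formula` on random subsets of decreasing size (fractions of the
#' full species count, rounded down), each subset guaranteed to contain at
#' least one member of every family: one representative per family is drawn
#' first, the remainder fills uniformly.
#'
#' @param records output of [assemble_records()].
#' @param tree a `phylo` object.
#' @param formula PGLS formula.
#' @param fractions subset fractions (default 0.9 down to 0.6).
#' @param replicates replicates per fraction (default 10).
#' @param coef_name coefficient to report.
#' @param seed RNG seed.
#' @param dist optional precomputed distances.
#' @return data.frame: fraction, replicate, n, estimate, p.
#' @export
subsample_robustness <- function(records, tree, formula,
                                 fractions = seq(0.9, 0.6, by = -0.1),
                                 replicates = 10, coef_name = "sds",
                                 seed = 1L, dist = NULL) {
  set.seed(seed)
  if (is.null(dist)) dist <- ape::cophenetic.phylo(tree)
  species <- intersect(rownames(records), tree$tip.label)
  fam <- records[species, "family"]
  n_all <- length(species)
  rows <- list()
  for (fr in fractions) {
    target <- floor(fr * n_all)
    if (target < length(unique(fam)))
      stop(sprintf("fraction %.2f leaves fewer species than families", fr))
    for (rep_i in seq_len(replicates)) {
      keep <- .family_subsample(species, fam, target)
      tr <- ape::drop.tip(tree, setdiff(tree$tip.label, keep))
      fit <- pgls_fit(formula, records[tr$tip.label, ], tr,
                      correlation = "OU",
                      dist = dist[tr$tip.label, tr$tip.label])
      rows[[length(rows) + 1]] <- data.frame(
        fraction = fr, replicate = rep_i, n = fit$n,
        estimate = unname(fit$coefficients[coef_name]),
        p = unname(fit$pval[coef_name]))
    }
  }
  do.call(rbind, rows)
}

#' Breeding windows against the consecutive-month null, by SDS group
#'
#' For every species, runs the enumerated consecutive-month null
#' ([null_window_test()]) on its range temperature series and records where
#' the observed breeding-window seasonality falls in the null. Species with
#' 12-month windows are excluded with a flag (the null is degenerate). Per
#' SDS group, a sign test asks whether observed seasonality falls below the
#' null median more often than half the time.
#'
#' @param records output of [assemble_records()].
#' @param study the study holding `grid` and `masks`.
#' @return list: `per_species` (data.frame with quantile, below_median,
#'   excluded), `group_tests` (data.frame per SDS group with sign-test p).
#' @export
window_null_summary <- function(records, study) {
  rows <- lapply(rownames(records), function(sp) {
    len <- records[sp, "window_length"]
    if (len >= 12)
      return(data.frame(species = sp, sds = records[sp, "sds"],
                        quantile = NA_real_, below_median = NA,
                        excluded = TRUE))
    series <- range_series(study$grid, study$masks[[sp]], "temperature")
    nt <- null_window_test(series, len,
                           observed_start = records[sp, "breed_start"])
    data.frame(species = sp, sds = records[sp, "sds"],
               quantile = nt$quantile,
               below_median = nt$observed < stats::median(nt$null),
               excluded = FALSE)
  })
  per_species <- do.call(rbind, rows)
  group_tests <- do.call(rbind, lapply(c(GSD = 0, TSD = 1), function(s) {
    sub <- per_species[!per_species$excluded & per_species$sds == s, ]
    k <- sum(sub$below_median)
    n <- nrow(sub)
    p <- if (n > 0) stats::binom.test(k, n, 0.5,
                                      alternative = "greater")$p.value
         else NA_real_
    data.frame(sds = s, n = n, n_below = k, p = p)
  }))
  group_tests$group <- rownames(group_tests)
  list(per_species = per_species, group_tests = group_tests)
}

#' Descriptive group summaries of the assembled records
#'
#' Counts, means, medians and interquartile ranges of each breeding-season
#' climate variable by sex-determination system: the descriptive arithmetic
#' behind the study's summary tables.
#'
#' @param records output of [assemble_records()].
#' @return data.frame: variable, sds, n, mean, median, q25, q75.
#' @export
descriptive_summary <- function(records) {
  vars <- c(.climate_vars, "window_length")
  rows <- list()
  for (v in vars) {
    for (s in c(0, 1)) {
      x <- records[records$sds == s, v]
      x <- x[!is.na(x)]
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, sds = s, n = length(x), mean = mean(x),
        median = stats::median(x), q25 = q[1], q75 = q[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
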