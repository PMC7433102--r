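#' Directed acyclic graph for a causal hypothesis
#'
#' @param name model label (e.g. `"A"`).
#' @param edges character vector of edges `"X -> Y"`, or a two-column
#'   (from, to) matrix.
#' @param vertices optional vertex set (defaults to those appearing in edges;
#'   isolated vertices can be added here).
#' @return object of class `causal_dag` with `name`, `vertices`, `edges`
#'   (from/to data.frame) and `order` (canonical topological order, ties
#'   broken lexicographically).
#' @export
causal_dag <- function(name, edges, vertices = NULL) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("edges must look like 'X -> Y'")
    em <- t(vapply(parts, function(p) trimws(p), character(2)))
  } else {
    em <- as.matrix(edges)
  }
  if (ncol(em) != 2) stop("edges must have a from and a to vertex")
  verts <- sort(unique(c(as.vector(em), vertices)))
  ed <- data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE)
  if (anyDuplicated(paste(ed$from, ed$to))) stop("duplicate edges")
  if (any(ed$from == ed$to)) stop("self-loops are not allowed")
  # Kahn topological sort with lexicographic tie-break
  order <- character(0)
  indeg <- vapply(verts, function(v) sum(ed$to == v), integer(1))
  remaining <- ed
  avail <- sort(verts[indeg == 0])
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    out <- remaining$from == v
    targets <- remaining$to[out]
    remaining <- remaining[!out, , drop = FALSE]
    for (t in targets) if (!t %in% remaining$to) avail <- sort(c(avail, t))
  }
  if (length(order) != length(verts)) stop("graph is cyclic, not a DAG")
  structure(list(name = name, vertices = verts, edges = ed, order = order),
            class = "causal_dag")
}

.parents <- function(dag, v) sort(dag$edges$from[dag$edges$to == v])

.adjacent <- function(dag, a, b) {
  any((dag$edges$from == a & dag$edges$to == b) |
      (dag$edges$from == b & dag$edges$to == a))
}

#' d-separation basis set of a DAG
#'
#' One conditional-independence claim per non-adjacent vertex pair: the pair
#' is independent given the union of both vertices' parents. Claims are
#' returned in canonical order (pairs ordered by the DAG's topological order)
#' and each claim records which vertex comes later in the causal order (the
#' regression response). The result does not depend on vertex insertion
#' order.
#'
#' @param dag a [causal_dag()].
#' @return list of claims: each a list `x`, `y` (the later vertex), `z`
#'   (conditioning set, possibly empty).
#' @export
basis_set <- function(dag) {
  ord <- dag$order
  claims <- list()
  nv <- length(ord)
  if (nv < 2) return(claims)
  for (i in seq_len(nv - 1)) {
    for (j in seq((i + 1), nv)) {
      a <- ord[i]; b <- ord[j]
      if (.adjacent(dag, a, b)) next
      z <- sort(setdiff(union(.parents(dag, a), .parents(dag, b)), c(a, b)))
      claims[[length(claims) + 1]] <- list(x = a, y = b, z = z)
    }
  }
  claims
}

#' Test one d-separation claim on comparative data
#'
#' Regresses the claim's later vertex (response) on the earlier vertex plus
#' the conditioning set, using Firth-penalized phylogenetic logistic
#' regression when the response is binary 0/1 and OU-PGLS otherwise, and
#' returns the p-value of the earlier vertex's coefficient.
#'
#' @param claim a claim from [basis_set()].
#' @param data data.frame of variables (rows = species, matching the tree).
#' @param tree a `phylo` object.
#' @param dist optional precomputed patristic distance matrix.
#' @return scalar p-value.
#' @export
test_claim <- function(claim, data, tree, dist = NULL) {
  vars <- c(claim$x, claim$y, claim$z)
  if (!all(vars %in% names(data)))
    stop("missing variables: ", paste(setdiff(vars, names(data)), collapse = ", "))
  rhs <- paste(c(claim$x, claim$z), collapse = " + ")
  f <- stats::as.formula(paste(claim$y, "~", rhs))
  yv <- data[[claim$y]]
  binary <- all(yv %in% c(0, 1))
  if (binary) {
    fit <- phylo_logistic_fit(f, data, tree, dist = dist)
    unname(fit$pval[claim$x])
  } else {
    fit <- pgls_fit(f, data, tree, correlation = "OU", dist = dist)
    unname(fit$pval[claim$x])
  }
}

#' Fisher's C statistic
#'
#' Combines the basis-set p-values: `C = -2 sum(log p)`, chi-square with
#' `2k` degrees of freedom when the DAG is correct. Zero p-values are clamped
#' to the smallest positive double with a warning.
#'
#' @param p_values numeric vector of p-values in (0, 1]; may be empty
#'   (saturated model: C = 0, p = 1).
#' @return list `C`, `df`, `p`.
#' @export
fisher_c <- function(p_values) {
  if (length(p_values) == 0)
    return(list(C = 0, df = 0L, p = 1))
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("zero p-value clamped to the smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df, p = stats::pchisq(C, df, lower.tail = FALSE))
}

#' C-statistic information criterion with small-sample correction
#'
#' `CICc = C + 2 q n / (n - 1 - q)` where `q` is the parameter count of the
#' path model and `n` the number of species.
#'
#' @param C Fisher's C.
#' @param q parameter count.
#' @param n sample size; must exceed `q + 1`.
#' @return scalar CICc.
#' @export
cicc <- function(C, q, n) {
  if (n <= q + 1) stop("need n > q + 1 for the small-sample correction")
  C + 2 * q * n / (n - 1 - q)
}

#' Rank path-model fits by CICc and attach Akaike-style weights
#'
#' `delta = CICc - min(CICc)`; `weight` is proportional to `exp(-delta / 2)`
#' and normalized over the whole set; models within `retain_delta` of the
#' best are flagged as retained.
#'
#' @param fits data.frame with a `CICc` column (one row per model).
#' @param retain_delta retention threshold (default 2).
#' @return `fits` with `delta`, `weight`, `retained` columns added.
#' @export
rank_and_weight <- function(fits, retain_delta = 2) {
  if (nrow(fits) < 1) stop("no fits to rank")
  fits$delta <- fits$CICc - min(fits$CICc)
  w <- exp(-fits$delta / 2)
  fits$weight <- w / sum(w)
  fits$retained <- fits$delta <= retain_delta
  fits
}

#' Weighted full-model averaging of standardized path coefficients
#'
#' Averages each edge's standardized coefficient over the retained models
#' with weights renormalized over the retained set. With `method = "full"`,
#' models lacking an edge contribute a coefficient of 0 for it (shrinking
#' edges absent from some supported models); `"conditional"` averages only
#' over models containing the edge.
#'
#' @param coef_table data.frame with columns `model`, `from`, `to`,
#'   `coefficient` (one row per edge per model).
#' @param weights named weights per retained model (will be renormalized).
#' @param method `"full"` (default) or `"conditional"`.
#' @return data.frame `from`, `to`, `coefficient`.
#' @export
average_paths <- function(coef_table, weights, method = c("full",
                                                          "conditional")) {
  method <- match.arg(method)
  if (length(weights) == 0) stop("empty retained set")
  weights <- weights / sum(weights)
  keep <- coef_table$model %in% names(weights)
  coef_table <- coef_table[keep, , drop = FALSE]
  edges <- unique(coef_table[, c("from", "to")])
  out <- lapply(seq_len(nrow(edges)), function(i) {
    sel <- coef_table$from == edges$from[i] & coef_table$to == edges$to[i]
    sub <- coef_table[sel, , drop = FALSE]
    w <- weights[sub$model]
    val <- if (method == "full") sum(w * sub$coefficient)
           else sum(w * sub$coefficient) / sum(w)
    data.frame(from = edges$from[i], to = edges$to[i], coefficient = val,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Built-in causal hypotheses
#'
#' `"ABCD"` returns the four three-variable scenarios over sex-determination
#' system (`sds`), breeding-season ambient temperature (`temp`) and
#' breeding-season length (`length`): A `sds -> temp -> length`; B
#' `sds -> length -> temp`; C `temp -> sds -> length`; D
#' `temp -> length -> sds`. `"life_history"` builds a user-supplied model set
#' over those vertices plus `lh_index` (the averaged life-history Z index);
#' the topologies are not hard-coded because competing life-history scenarios
#' are study-specific, so `topologies` (a named list of edge vectors) is
#' required.
#'
#' @param set `"ABCD"` or `"life_history"`.
#' @param topologies named list of edge vectors for `"life_history"`.
#' @return list of [causal_dag()] objects.
#' @export
builtin_hypotheses <- function(set = c("ABCD", "life_history"),
                               topologies = NULL) {
  set <- match.arg(set)
  if (set == "ABCD") {
    return(list(
      causal_dag("A", c("sds -> temp", "temp -> length")),
      causal_dag("B", c("sds -> length", "length -> temp")),
      causal_dag("C", c("temp -> sds", "sds -> length")),
      causal_dag("D", c("temp -> length", "length -> sds"))
    ))
  }
  if (is.null(topologies) || is.null(names(topologies)))
    stop("life_history hypotheses are user-configurable: supply a named ",
         "list of edge vectors over sds/temp/length/lh_index")
  allowed <- c("sds", "temp", "length", "lh_index")
  dags <- Map(causal_dag, names(topologies), topologies)
  for (d in dags)
    if (!all(d$vertices %in% allowed))
      stop("life_history vertices must be among: ",
           paste(allowed, collapse = ", "))
  unname(dags)
}

#' Fit and compare a set of causal path models
#'
#' For each DAG: tests every d-separation claim of its basis set
#' ([test_claim()]), combines them into Fisher's C and its chi-square test,
#' computes CICc with `q` equal to the number of directed edges (or edges +
#' vertices with `q_method = "edges+vertices"`), then ranks models by CICc,
#' flags those within `retain_delta` of the best, estimates standardized path
#' coefficients (each vertex regressed on its parents; continuous variables
#' z-scored, binary ones left 0/1) and returns the weighted full average over
#' the retained models.
#'
#' @param dags list of [causal_dag()] objects.
#' @param data data.frame of the DAG variables (rows = species).
#' @param tree a `phylo` object.
#' @param q_method parameter-count convention.
#' @param retain_delta CICc retention threshold (default 2).
#' @param dist optional precomputed patristic distance matrix.
#' @param standardize z-score continuous variables before fitting.
#' @param coefficients also estimate and average the standardized path
#'   coefficients (default TRUE); turn off to rank models only, e.g. in
#'   simulation loops.
#' @return object of class `path_analysis`: `models` (data.frame with C, df,
#'   p, q, CICc, delta, weight, retained), `claims`, `coefficients` (per
#'   model per edge), `averaged` (data.frame of averaged edges).
#' @export
fit_path_models <- function(dags, data, tree,
                            q_method = c("edges", "edges+vertices"),
                            retain_delta = 2, dist = NULL,
                            standardize = TRUE, coefficients = TRUE) {
  q_method <- match.arg(q_method)
  if (is.null(dist)) dist <- ape::cophenetic.phylo(tree)
  data <- .align_rows(as.data.frame(data), tree)
  vars <- unique(unlist(lapply(dags, `[[`, "vertices")))
  if (standardize) {
    for (v in vars) {
      if (!all(data[[v]] %in% c(0, 1)))
        data[[v]] <- as.numeric(scale(data[[v]]))
    }
  }
  n <- nrow(data)
  rows <- list(); claim_rows <- list(); coef_rows <- list()
  for (dag in dags) {
    claims <- basis_set(dag)
    pvals <- vapply(claims, test_claim, numeric(1), data = data, tree = tree,
                    dist = dist)
    fc <- fisher_c(pvals)
    q <- nrow(dag$edges) +
      if (q_method == "edges+vertices") length(dag$vertices) else 0L
    rows[[dag$name]] <- data.frame(
      model = dag$name, C = fc$C, df = fc$df, C_p = fc$p, q = q,
      CICc = cicc(fc$C, q, n), stringsAsFactors = FALSE)
    if (length(claims) > 0)
      claim_rows[[dag$name]] <- data.frame(
        model = dag$name,
        x = vapply(claims, `[[`, character(1), "x"),
        y = vapply(claims, `[[`, character(1), "y"),
        z = vapply(claims, function(cl) paste(cl$z, collapse = ","),
                   character(1)),
        p = pvals, stringsAsFactors = FALSE)
    # standardized path coefficients: each vertex on its parents
    if (coefficients) for (v in dag$vertices) {
      pa <- .parents(dag, v)
      if (length(pa) == 0) next
      f <- stats::as.formula(paste(v, "~", paste(pa, collapse = " + ")))
      if (all(data[[v]] %in% c(0, 1))) {
        fit <- phylo_logistic_fit(f, data, tree, dist = dist)
      } else {
        fit <- pgls_fit(f, data, tree, correlation = "OU", dist = dist)
      }
      coef_rows[[paste(dag$name, v)]] <- data.frame(
        model = dag$name, from = pa, to = v,
        coefficient = unname(fit$coefficients[pa]), stringsAsFactors = FALSE)
    }
  }
  models <- rank_and_weight(do.call(rbind, rows), retain_delta)
  rownames(models) <- NULL
  coefs <- do.call(rbind, coef_rows)
  averaged <- NULL
  if (coefficients) {
    rownames(coefs) <- NULL
    w <- stats::setNames(models$weight, models$model)[models$retained]
    averaged <- average_paths(coefs, w, method = "full")
  }
  structure(list(models = models,
                 claims = do.call(rbind, claim_rows),
                 coefficients = coefs, averaged = averaged, n = n),
            class = "path_analysis")
}

#' @export
print.path_analysis <- function(x, ...) {
  cat("Phylogenetic path analysis (d-separation), n =", x$n, "\n")
  print(x$models, digits = 4)
  cat("\nAveraged standardized paths over retained models:\n")
  print(x$averaged, digits = 3)
  invisible(x)
}
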