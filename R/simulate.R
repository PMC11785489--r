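#' Configuration for the synthetic repertoire generator
#'
#' Collects every knob of the simulator with defaults chosen to emulate the
#' statistical structure the package's analyses assume: multi-donor
#' repertoires with geometric clonal expansion, public clonotypes shared
#' across exactly two donors, CDR3 lengths inside the QC windows, binary
#' cell states drawn from a linear logit on the (scaled) TCR features with
#' donor random intercepts, cluster-structured labels for the twin
#' analysis, and Dextramer counts with technical covariates and spiked
#' binder populations.
#'
#' @param n_donors Number of donors.
#' @param cells_per_donor Cells sampled per donor.
#' @param clone_geom_p Geometric parameter for clone sizes
#'   (`size = 1 + rgeom(p)`; smaller p means more expansion).
#' @param public_rate Fraction of clones copied into a second donor as a
#'   public clonotype.
#' @param len_probs_a,len_probs_b CDR3 length laws (named probability
#'   vectors over 10:17 and 11:18; junction-inclusive lengths).
#' @param n_true_features,effect_size Number of nonzero true feature
#'   weights and their magnitude (logit units per scaled-feature sd); signs
#'   are random. True features are drawn among CDR3 positional features on
#'   slots occupied at every admissible junction length: such slots carry no
#'   gaps, so the configured effect size is realized exactly, and junction
#'   residues vary cell by cell, so the sparse truth is identifiable
#'   (germline CDR1/CDR2 features are collinear at the V-gene level).
#' @param intercept Baseline logit of the target state.
#' @param donor_sd Standard deviation of donor random intercepts.
#' @param cluster_labels,cluster_freqs Cluster label set and base
#'   frequencies for the twin cohort.
#' @param concordance_boost Probability that a twin's second member is
#'   forced into the first member's cluster (0 = pure null).
#' @param dex Dextramer block: list with `n_dex`, `n_controls`, `bg_mu`,
#'   `bg_theta`, `spike`, `binder_frac`, `nc_coef`, `tcr_coef`, `cd3_coef`,
#'   `cd8_coef`, `donor_coef_sd`.
#' @param gene_table V-gene table (default: bundled synthetic table).
#' @param registry Feature registry (default: [build_registry()]).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_donors = 10L, cells_per_donor = 300L,
                       clone_geom_p = 0.6, public_rate = 0.02,
                       len_probs_a = stats::setNames(
                         c(.05, .10, .15, .20, .20, .15, .10, .05), 10:17),
                       len_probs_b = stats::setNames(
                         c(.05, .10, .15, .20, .20, .15, .10, .05), 11:18),
                       n_true_features = 10L, effect_size = 0.5,
                       intercept = -1, donor_sd = 0.5,
                       cluster_labels = paste0("A", 1:9),
                       cluster_freqs = c(.22, .18, .14, .12, .10, .08, .07,
                                         .05, .04),
                       concordance_boost = 0,
                       dex = list(n_dex = 10L, n_controls = 6L, bg_mu = 3,
                                  bg_theta = 5, spike = 20,
                                  binder_frac = 0.05, nc_coef = 0.02,
                                  tcr_coef = 0.3, cd3_coef = 0.1,
                                  cd8_coef = 0.1, donor_coef_sd = 0.1),
                       gene_table = NULL, registry = NULL) {
  if (public_rate < 0 || public_rate > 1) .stopf("public_rate must be in [0,1]")
  if (concordance_boost < 0 || concordance_boost > 1)
    .stopf("concordance_boost must be in [0,1]")
  if (abs(sum(len_probs_a) - 1) > 1e-8 || abs(sum(len_probs_b) - 1) > 1e-8)
    .stopf("length laws must sum to 1")
  if (abs(sum(cluster_freqs) - 1) > 1e-8)
    .stopf("cluster frequencies must sum to 1")
  if (clone_geom_p <= 0 || clone_geom_p > 1) .stopf("clone_geom_p must be in (0,1]")
  if (n_donors < 1L || cells_per_donor < 1L) .stopf("cohort sizes must be positive")
  if (is.null(gene_table)) gene_table <- read_gene_table()
  if (is.null(registry)) registry <- build_registry()
  lens_a <- as.integer(names(len_probs_a)); lens_b <- as.integer(names(len_probs_b))
  if (any(lens_a < 10L | lens_a > 17L) || any(lens_b < 11L | lens_b > 18L))
    .stopf("length laws must stay inside the QC windows (a 10-17, b 11-18)")
  structure(list(n_donors = as.integer(n_donors),
                 cells_per_donor = as.integer(cells_per_donor),
                 clone_geom_p = clone_geom_p, public_rate = public_rate,
                 len_probs_a = len_probs_a, len_probs_b = len_probs_b,
                 n_true_features = as.integer(n_true_features),
                 effect_size = effect_size, intercept = intercept,
                 donor_sd = donor_sd, cluster_labels = cluster_labels,
                 cluster_freqs = cluster_freqs,
                 concordance_boost = concordance_boost, dex = dex,
                 gene_table = gene_table, registry = registry),
            class = "sim_config")
}

# draw clone sizes until a donor's cell budget is filled exactly
.draw_clone_sizes <- function(n_cells, p) {
  sizes <- integer(0)
  while (sum(sizes) < n_cells)
    sizes <- c(sizes, 1L + stats::rgeom(max(16L, n_cells %/% 2L), p))
  cum <- cumsum(sizes)
  k <- which(cum >= n_cells)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n_cells)
  sizes[sizes > 0L]
}

# random CDR3 junction strings with C...F anchors, unique across the cohort
.draw_cdr3 <- function(n, len_probs, existing = character(0)) {
  lens <- as.integer(names(len_probs))
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    L <- sample(lens, length(need), replace = TRUE, prob = len_probs)
    inner <- vapply(L - 2L, function(k)
      paste(sample(.aa_letters, k, replace = TRUE), collapse = ""),
      character(1))
    cand <- paste0("C", inner, "F")
    ok <- !duplicated(cand) & !(cand %in% existing) & !(cand %in% out)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

# CDR3 positional features on slots occupied at every admissible junction
# length. Ground truth is planted on the junction only: CDR1/CDR2 features
# are functions of the finite V-gene vocabulary, hence collinear at the gene
# level, and a sparse truth there is not identifiable by any method. CDR3
# residues vary cell by cell, so recovery of a sparse junction truth is
# well-posed.
.universal_positional <- function(config) {
  reg <- config$registry
  min_len <- c(
    CDR3a = min(as.integer(names(config$len_probs_a))) - 2L,
    CDR3b = min(as.integer(names(config$len_probs_b))) - 2L
  )
  fe <- reg$features
  which(fe$kind == "position_atchley" & fe$loop %in% names(min_len) &
          mapply(function(lp, s)
            lp %in% names(min_len) &&
              s %in% .occupied_slots(min_len[lp], reg$slots[lp]),
            fe$loop, fe$slot))
}

#' Simulate a multi-donor TCR repertoire with known ground truth
#'
#' Draws clones per donor (geometric sizes), samples V/J genes from the
#' configured gene table and CDR3 junctions from the configured length laws
#' (all inside the QC windows, so the output passes [pair_and_qc()] with
#' zero removals), copies a fraction of clonotypes verbatim into a second
#' donor (public TCR twins), and draws each cell's binary state from
#' `Bernoulli(plogis(w . x_clone + b + u_donor))` where `x_clone` is the
#' clone's scaled feature vector and `w` the planted sparse weight vector.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is bit-reproducible per
#'   `(config, seed)`.
#' @return List with `tcrs` (per-cell paired TCRs), `cells` (per-cell
#'   metadata: `cell_id`, `donor_id`, `clonotype_key`, `state`,
#'   `state_label`), and `truth` (planted weight vector and indices,
#'   intercept, donor intercepts, public clonotype keys, clone
#'   probabilities).
#' @export
simulate_repertoire <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    gt <- config$gene_table
    va_pool <- gt$v_gene[gt$locus == "alpha" & !gt$pseudogene]
    vb_pool <- gt$v_gene[gt$locus == "beta" & !gt$pseudogene]
    ja_pool <- paste0("TRAJS", 1:8)
    jb_pool <- paste0("TRBJS", 1:8)
    donors <- sprintf("D%02d", seq_len(config$n_donors))

    sizes <- lapply(donors, function(d)
      .draw_clone_sizes(config$cells_per_donor, config$clone_geom_p))
    n_clones <- sum(lengths(sizes))
    clones <- data.frame(
      donor_id = rep(donors, lengths(sizes)),
      size = unlist(sizes),
      va = sample(va_pool, n_clones, replace = TRUE),
      ja = sample(ja_pool, n_clones, replace = TRUE),
      vb = sample(vb_pool, n_clones, replace = TRUE),
      jb = sample(jb_pool, n_clones, replace = TRUE),
      cdr3a = .draw_cdr3(n_clones, config$len_probs_a),
      stringsAsFactors = FALSE
    )
    clones$cdr3b <- .draw_cdr3(n_clones, config$len_probs_b,
                               existing = clones$cdr3a)
    clones$cell_id <- sprintf("clone%05d", seq_len(n_clones))

    # public clonotypes: copy into one other donor as a singleton clone
    n_public <- round(config$public_rate * n_clones)
    public_keys <- character(0)
    if (n_public > 0 && config$n_donors >= 2L) {
      src <- sample.int(n_clones, n_public)
      copies <- clones[src, , drop = FALSE]
      copies$donor_id <- vapply(copies$donor_id, function(d)
        sample(setdiff(donors, d), 1L), character(1))
      copies$size <- 1L
      copies$cell_id <- sprintf("public%05d", seq_len(n_public))
      clones <- rbind(clones, copies)
      public_keys <- clonotype_key(copies)
    }
    clones$key <- clonotype_key(clones)

    feats <- featurize_tcrs(clones, gt, config$registry)
    scaling <- fit_scaling(feats)
    Xs <- apply_scaling(feats, scaling)$x

    eligible <- .universal_positional(config)
    idx <- sample(eligible, config$n_true_features)
    w_sign <- sample(c(-1, 1), config$n_true_features, replace = TRUE)
    w <- numeric(ncol(Xs))
    w[idx] <- w_sign * config$effect_size
    names(w) <- config$registry$features$name

    u <- stats::rnorm(length(donors), 0, config$donor_sd)
    names(u) <- donors
    logit <- as.vector(Xs %*% w) + config$intercept + u[clones$donor_id]
    p_clone <- stats::plogis(logit)

    rows <- rep(seq_len(nrow(clones)), clones$size)
    cells <- clones[rows, c("donor_id", "va", "ja", "cdr3a", "vb", "jb",
                            "cdr3b", "key"), drop = FALSE]
    cells$cell_id <- sprintf("%s_c%05d", cells$donor_id,
                             stats::ave(seq_along(rows), cells$donor_id,
                                        FUN = seq_along))
    cells$state <- stats::rbinom(nrow(cells), 1L, p_clone[rows])
    rownames(cells) <- NULL

    tcrs <- cells[c("cell_id", "donor_id", "va", "ja", "cdr3a",
                    "vb", "jb", "cdr3b")]
    meta <- data.frame(cell_id = cells$cell_id, donor_id = cells$donor_id,
                       clonotype_key = cells$key, state = cells$state,
                       state_label = ifelse(cells$state == 1L, "pos", "neg"),
                       stringsAsFactors = FALSE)
    list(tcrs = tcrs, cells = meta,
         truth = list(weights = w, true_idx = idx,
                      intercept = config$intercept, donor_intercepts = u,
                      public_keys = public_keys,
                      clone_prob = stats::setNames(p_clone, clones$key)))
  })
}

#' Simulate a twin cohort with planted concordance
#'
#' Builds a multi-donor cohort of clones with cluster-structured state
#' labels (all cells of a clone share the clone's cluster, drawn from the
#' configured base frequencies) and plants public clonotypes in exactly two
#' donors. The second twin member's cluster is forced to match the first
#' with probability `concordance_boost`; at 0 the twins follow the base
#' multinomial independently, reproducing the sampling null of the
#' concordance test.
#'
#' @param config A [sim_config()] (uses `cluster_labels`, `cluster_freqs`,
#'   `public_rate`, `concordance_boost`).
#' @param seed Integer seed.
#' @return List with `cells` (columns `cell_id`, `donor_id`,
#'   `clonotype_key`, `state_label`) and `truth` (planted twin keys and the
#'   boost).
#' @export
simulate_twin_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    rep_sim <- simulate_repertoire(config, seed = seed + 1L)
    cells <- rep_sim$cells
    keys <- unique(cells$clonotype_key)
    clone_label <- stats::setNames(
      sample(config$cluster_labels, length(keys), replace = TRUE,
             prob = config$cluster_freqs), keys)
    cells$state_label <- clone_label[cells$clonotype_key]

    twin_keys <- rep_sim$truth$public_keys
    for (k in twin_keys) {
      i <- which(cells$clonotype_key == k)
      d <- cells$donor_id[i]
      donors_k <- unique(d)
      if (length(donors_k) != 2L) next
      first <- donors_k[1]
      if (stats::runif(1) < config$concordance_boost) {
        cells$state_label[i] <- cells$state_label[i[d == first]][1]
      } else {
        cells$state_label[i[d != first]] <-
          sample(config$cluster_labels, 1L, prob = config$cluster_freqs)
      }
    }
    cells$state <- NULL
    list(cells = cells,
         truth = list(twin_keys = twin_keys,
                      concordance_boost = config$concordance_boost,
                      clone_label = clone_label))
  })
}

#' Simulate a Dextramer panel with planted binders
#'
#' Negative-control counts are negative binomial draws; each target
#' dextramer's log-mean is linear in the negative-control counts and the
#' technical covariates (TCR/CD3/CD8 expression, donor effects), mirroring
#' the background model, and planted binder cells have their mean
#' multiplied by the spike factor.
#'
#' @param config A [sim_config()] (uses the `dex` block).
#' @param seed Integer seed.
#' @param cells Per-cell metadata (needs `cell_id`, `donor_id`), e.g. from
#'   [simulate_repertoire()].
#' @return List with `panel` (a [dextramer_panel()]) and `truth` (binder
#'   matrix and the generating coefficients).
#' @export
simulate_dextramer <- function(config, seed, cells) {
  stopifnot(inherits(config, "sim_config"))
  dx <- config$dex
  n <- nrow(cells)
  .with_seed(seed, {
    nc <- matrix(stats::rnbinom(n * dx$n_controls, mu = dx$bg_mu,
                                size = dx$bg_theta),
                 n, dx$n_controls)
    covs <- data.frame(
      tcr_exp = stats::rnorm(n, 2, 0.5),
      cd3_exp = stats::rnorm(n, 0, 1),
      cd8_exp = stats::rnorm(n, 0, 1),
      donor_id = cells$donor_id,
      stringsAsFactors = FALSE
    )
    donors <- sort(unique(cells$donor_id))
    donor_eff <- stats::setNames(
      c(0, stats::rnorm(length(donors) - 1L, 0, dx$donor_coef_sd)), donors)

    targets <- matrix(0L, n, dx$n_dex)
    binders <- matrix(FALSE, n, dx$n_dex)
    base_log <- log(dx$bg_mu) +
      dx$nc_coef * rowSums(nc - dx$bg_mu) +
      dx$tcr_coef * (covs$tcr_exp - 2) +
      dx$cd3_coef * covs$cd3_exp + dx$cd8_coef * covs$cd8_exp +
      donor_eff[cells$donor_id]
    for (j in seq_len(dx$n_dex)) {
      is_binder <- stats::runif(n) < dx$binder_frac
      mu <- exp(base_log) * ifelse(is_binder, dx$spike, 1)
      targets[, j] <- stats::rnbinom(n, mu = mu, size = dx$bg_theta)
      binders[, j] <- is_binder
    }
    counts <- cbind(nc, targets)
    colnames(counts) <- c(sprintf("NC%02d", seq_len(dx$n_controls)),
                          sprintf("DEX%02d", seq_len(dx$n_dex)))
    rownames(counts) <- cells$cell_id
    colnames(binders) <- sprintf("DEX%02d", seq_len(dx$n_dex))
    panel <- dextramer_panel(counts,
                             controls = sprintf("NC%02d", seq_len(dx$n_controls)),
                             covariates = covs)
    list(panel = panel,
         truth = list(binders = binders, donor_effects = donor_eff,
                      coefs = dx))
  })
}
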