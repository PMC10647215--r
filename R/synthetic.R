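# Synthetic data generation: CDS sequences, mutation sets under
# specified selection, labelled source-domain and covariate-shifted
# unlabelled target-domain feature tables, and toy alignments with dated
# trees. Every generator is a pure function of its arguments and seed.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Generate a random coding sequence
#'
#' Starts with ATG, ends with a stop codon, contains no internal stop,
#' and targets the requested GC fraction by weighting sense codons by
#' their base composition.
#'
#' @param n_codons Total codon count including start and stop (>= 2).
#' @param gc_fraction Target GC fraction in (0, 1).
#' @param seed Optional RNG seed for reproducibility.
#' @return Coding DNA string of length `3 * n_codons`.
#' @export
gen_cds <- function(n_codons, gc_fraction = 0.5, seed = NULL) {
  stopifnot(n_codons >= 2, gc_fraction > 0, gc_fraction < 1)
  with_seed(seed, {
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    stops <- names(code)[code == "*"]
    p_base <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
                G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    codon_w <- function(codons) {
      vapply(strsplit(codons, ""), function(b) prod(p_base[b]),
             numeric(1))
    }
    body <- if (n_codons > 2) {
      sample(sense, n_codons - 2, replace = TRUE, prob = codon_w(sense))
    } else character(0)
    stop_codon <- sample(stops, 1, prob = codon_w(stops))
    paste(c("ATG", body, stop_codon), collapse = "")
  })
}

#' Sample mutations for one gene under specified selection
#'
#' Class counts are multinomial with probabilities proportional to
#' `(p_syn, exp(log_omega) * p_mis, exp(log_phi) * p_trunc)` from the
#' gene's saturated expectation. Positions are drawn from the per-site
#' neutral class weights, except that a fraction `h` of missense
#' mutations is placed at one designated hotspot position (drawn by
#' missense opportunity), and truncating positions can be restricted to
#' the first `trunc_early` fraction of the protein (the
#' tumour-suppressor archetype).
#'
#' @param cds Coding DNA string.
#' @param expectation [enumerate_saturated_mutations()] of the same CDS.
#' @param log_omega,log_phi True log selection coefficients.
#' @param h Hotspot fraction of missense mutations in `[0, 1]`.
#' @param n_mutations Total mutations to draw (>= 1).
#' @param trunc_early Optional fraction of the protein (from the N
#'   terminus) to which truncating mutations are confined.
#' @param gene Gene symbol for the records.
#' @param n_samples Number of tumour samples mutations are spread over.
#' @param seed Optional RNG seed.
#' @return Data frame of mutation records (`gene`, `sample`,
#'   `protein_pos`, `consequence`).
#' @export
gen_mutations <- function(cds, expectation, log_omega = 0, log_phi = 0,
                          h = 0, n_mutations, trunc_early = NULL,
                          gene = "gene1", n_samples = 10, seed = NULL) {
  if (n_mutations < 1) stop("n_mutations must be >= 1", call. = FALSE)
  stopifnot(h >= 0, h <= 1)
  with_seed(seed, {
    p <- expectation$p
    w <- expectation$site_weights
    probs <- c(p[["syn"]], exp(log_omega) * p[["mis"]],
               exp(log_phi) * p[["trunc"]])
    counts <- stats::rmultinom(1, n_mutations, probs)[, 1]
    draw_pos <- function(k, weights, what) {
      if (k == 0) return(integer(0))
      if (sum(weights) <= 0) {
        stop(sprintf("no %s mutational opportunity in CDS", what),
             call. = FALSE)
      }
      sample(w$protein_pos, k, replace = TRUE, prob = weights)
    }
    pos_syn <- draw_pos(counts[1], w$syn, "synonymous")
    n_hot <- round(h * counts[2])
    hotspot <- if (counts[2] > 0 && sum(w$mis) > 0) {
      sample(w$protein_pos, 1, prob = w$mis)
    } else NA_integer_
    pos_mis <- c(rep(hotspot, n_hot),
                 draw_pos(counts[2] - n_hot, w$mis, "missense"))
    w_trunc <- w$trunc
    if (!is.null(trunc_early)) {
      cutoff <- ceiling(trunc_early * expectation$n_codons)
      early <- w$protein_pos <= cutoff
      if (any(w_trunc[early] > 0)) w_trunc[!early] <- 0
    }
    pos_trunc <- draw_pos(counts[3], w_trunc, "truncating")
    records <- data.frame(
      gene = gene,
      protein_pos = c(pos_syn, pos_mis, pos_trunc),
      consequence = rep(c("synonymous", "missense", "nonsense"), counts),
      stringsAsFactors = FALSE
    )
    records$sample <- paste0("S", sample.int(n_samples, nrow(records),
                                             replace = TRUE))
    records[c("gene", "sample", "protein_pos", "consequence")]
  })
}

#' Synthetic benchmark scenario
#'
#' Parameters of the source/target domain generator. Defaults encode the
#' three gene archetypes: oncogenes under positive missense selection
#' with a mutation hotspot, tumour suppressors under positive truncating
#' selection with early truncations, and passengers near neutrality; the
#' target domain adds a location shift (in source standard deviations)
#' on a subset of features to emulate the accelerated, genetically
#' engineered background of mouse tumour models.
#'
#' @param n_source_per_class,n_target_per_class Genes per class in each
#'   domain.
#' @param archetypes Named list (OG/TSG/PG) of parameter lists:
#'   `log_omega` and `log_phi` as `c(mean, sd)` of truncated normals on
#'   `[-5, 5]`, `h` hotspot fraction, `trunc_early` truncation-position
#'   bias (NULL for none).
#' @param rate_profiles Named list (OG/TSG/PG) of
#'   `c(meanlog_gene, meanlog_summit, sdlog)` for the lognormal
#'   long-term rate draws (s/bys); driver-mutated sites are more
#'   conserved than passenger-mutated ones.
#' @param mutations_min,mutations_mu,mutations_size Shifted negative
#'   binomial for per-gene mutation counts:
#'   `min + NB(mu, size)`.
#' @param protein_codons `c(meanlog, sdlog, min, max)` of the lognormal
#'   protein size draw (codons).
#' @param shift_features,shift_delta Covariate shift: features receiving
#'   a `+shift_delta` source-SD location shift in the target domain.
#' @param seed Mandatory RNG seed.
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    n_source_per_class = 150, n_target_per_class = 60,
    archetypes = list(
      OG = list(log_omega = c(3.5, 1), log_phi = c(-3.5, 1), h = 0.5,
                trunc_early = NULL),
      TSG = list(log_omega = c(0.5, 1), log_phi = c(3.5, 1), h = 0,
                 trunc_early = 0.4),
      PG = list(log_omega = c(0, 0.5), log_phi = c(0, 0.5), h = 0,
                trunc_early = NULL)),
    rate_profiles = list(
      OG = c(meanlog_gene = log(0.6), meanlog_summit = log(0.4),
             sdlog = 0.4),
      TSG = c(meanlog_gene = log(0.6), meanlog_summit = log(0.5),
              sdlog = 0.4),
      PG = c(meanlog_gene = log(1.2), meanlog_summit = log(1.2),
             sdlog = 0.4)),
    mutations_min = 5, mutations_mu = 8, mutations_size = 2,
    protein_codons = c(meanlog = log(400), sdlog = 0.4, min = 100,
                       max = 1500),
    shift_features = c("E_gene", "R_peak", "C_summit"),
    shift_delta = 0.5,
    seed) {
  if (missing(seed)) stop("scenario seed is mandatory", call. = FALSE)
  structure(list(
    n_source_per_class = n_source_per_class,
    n_target_per_class = n_target_per_class,
    archetypes = archetypes, rate_profiles = rate_profiles,
    mutations_min = mutations_min, mutations_mu = mutations_mu,
    mutations_size = mutations_size, protein_codons = protein_codons,
    shift_features = shift_features, shift_delta = shift_delta,
    seed = seed), class = "synthetic_scenario")
}

rtrunc_norm <- function(n, mean, sd, lo = -5, hi = 5) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# One synthetic gene: CDS -> mutations -> features. Runs inside the
# caller's RNG stream.
gen_gene_row <- function(class, scenario, gene) {
  arch <- scenario$archetypes[[class]]
  pc <- scenario$protein_codons
  n_codons <- round(min(pc[["max"]], max(pc[["min"]],
                    stats::rlnorm(1, pc[["meanlog"]], pc[["sdlog"]]))))
  cds <- gen_cds(n_codons, gc_fraction = 0.45)
  expectation <- enumerate_saturated_mutations(cds)
  lo <- rtrunc_norm(1, arch$log_omega[1], arch$log_omega[2])
  lp <- rtrunc_norm(1, arch$log_phi[1], arch$log_phi[2])
  n_mut <- scenario$mutations_min +
    stats::rnbinom(1, size = scenario$mutations_size,
                   mu = scenario$mutations_mu)
  rec <- gen_mutations(cds, expectation, log_omega = lo, log_phi = lp,
                       h = arch$h, n_mutations = n_mut,
                       trunc_early = arch$trunc_early, gene = gene)
  est <- estimate_selection(
    c(n_syn = sum(rec$consequence == "synonymous"),
      n_mis = sum(rec$consequence == "missense"),
      n_trunc = sum(rec$consequence %in% c("nonsense", "frameshift"))),
    expectation)
  rp <- scenario$rate_profiles[[class]]
  protein_length <- expectation$n_codons
  data.frame(
    gene = gene,
    E_gene = stats::rlnorm(1, rp[["meanlog_gene"]], rp[["sdlog"]]),
    E_summit = stats::rlnorm(1, rp[["meanlog_summit"]], rp[["sdlog"]]),
    log_omega = est$log_omega, log_phi = est$log_phi,
    t(mutation_fractions(rec)),
    t(hotspot_features(rec)),
    t(truncation_length(rec, protein_length)),
    stringsAsFactors = FALSE
  )
}

#' Generate labelled source and shifted unlabelled target feature tables
#'
#' Each gene runs through the full pipeline — random CDS, saturated
#' expectation, mutation sampling under its class archetype, selection
#' estimation, feature extraction — then target rows receive the
#' scenario's covariate shift. Hidden target labels are returned for
#' evaluation only.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List: `source` (list `features`, `labels`), `target` (list
#'   `features`, `labels_hidden`), `scenario`.
#' @export
gen_domain_tables <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (scenario$n_source_per_class < 2) {
    stop("training infeasible: need at least 2 source genes per class",
         call. = FALSE)
  }
  with_seed(scenario$seed, {
    make_domain <- function(n_per_class, prefix) {
      rows <- list()
      labels <- character(0)
      for (cl in DRIVER_CLASSES) {
        for (i in seq_len(n_per_class)) {
          rows[[length(rows) + 1L]] <-
            gen_gene_row(cl, scenario, sprintf("%s_%s_%03d", prefix, cl, i))
          labels <- c(labels, cl)
        }
      }
      list(features = do.call(rbind, rows),
           labels = factor(labels, levels = DRIVER_CLASSES))
    }
    source <- make_domain(scenario$n_source_per_class, "src")
    target <- make_domain(scenario$n_target_per_class, "tgt")
    for (f in scenario$shift_features) {
      target$features[[f]] <- target$features[[f]] +
        scenario$shift_delta * stats::sd(source$features[[f]])
    }
    list(source = source,
         target = list(features = target$features,
                       labels_hidden = target$labels),
         scenario = scenario)
  })
}

#' Simulate a toy protein alignment down a dated tree
#'
#' Draws a random coalescent tree scaled to the requested depth, then
#' evolves each column independently: substitutions occur along each
#' branch as a Poisson process with the column's rate (s/bys), each
#' substitution jumping to a different uniformly drawn residue.
#'
#' @param n_species Number of leaves.
#' @param depth_bys Tree depth (root to tip) in billions of years.
#' @param rate_profile Numeric vector of per-column substitution rates
#'   (s/bys); its length sets the alignment width.
#' @param seed Optional RNG seed.
#' @return List: `alignment` (character matrix, species x columns,
#'   reference species `"sp1"`), `tree` (`ape::phylo`, branch lengths in
#'   bys).
#' @export
gen_toy_phylo <- function(n_species = 6, depth_bys = 0.5, rate_profile,
                          seed = NULL) {
  with_seed(seed, {
    tree <- ape::rcoal(n_species, tip.label = paste0("sp", seq_len(n_species)))
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * depth_bys / depth
    n_nodes <- n_species + tree$Nnode
    tree <- stats::reorder(tree, "cladewise")   # parents before children
    edge <- tree$edge
    aln <- matrix("", n_species, length(rate_profile),
                  dimnames = list(tree$tip.label, NULL))
    for (j in seq_along(rate_profile)) {
      state <- character(n_nodes)
      state[n_species + 1L] <- sample(AA_ALPHABET, 1)
      for (e in seq_len(nrow(edge))) {
        parent_state <- state[edge[e, 1]]
        n_sub <- stats::rpois(1, rate_profile[j] * tree$edge.length[e])
        s <- parent_state
        if (n_sub > 0) {
          for (k in seq_len(n_sub)) s <- sample(setdiff(AA_ALPHABET, s), 1)
        }
        state[edge[e, 2]] <- s
      }
      aln[, j] <- state[seq_len(n_species)]
    }
    list(alignment = aln, tree = tree)
  })
}
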