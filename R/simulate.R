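#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data generator: the
#' four-condition negative-binomial count model with planted interaction
#' classes, and the synthetic genome with enhancer clusters, planted motifs
#' and condition-dependent coverage encoding assisted-loading logic.
#'
#' The count model: a gene's untreated mean is \code{baseline_mean}; an
#' inducing single hormone multiplies it by \code{effect_single}; an
#' additive gene's dual delta is the sum of the two single deltas; a
#' synergistic gene's dual delta is \code{synergy_factor} times that sum;
#' an antagonized gene keeps only \code{antagonism_residual} of its single
#' delta in the dual treatment. Counts are NB with variance
#' \eqn{\mu + \alpha \mu^2} (shared dispersion \code{dispersion}).
#'
#' The genome: \code{n_clusters} enhancer clusters, each with
#' \code{units_per_cluster_range} DNase units of \code{unit_length} bp
#' packed into \code{cluster_span} bp; one unit per cluster hosts a GR
#' binding site. Assisted sites carry a planted weak GRE plus a CRE in the
#' same and/or a sibling unit; unassisted sites carry a strong GRE and no
#' CRE; inactive sites carry no motif. Coverage is Poisson background at
#' \code{background_rate} tags/bp plus triangular peaks whose height is
#' \code{peak_enrichment} times the background, following the assay rules
#' (see [simulate_coverage()]).
#'
#' @param seed master RNG seed; every derived stream is a deterministic
#'   function of it, so the same config is bit-identical across runs.
#' @param replicates replicates per condition.
#' @param n_per_class named gene counts per interaction class.
#' @param baseline_mean expected untreated count.
#' @param dispersion NB dispersion alpha.
#' @param effect_single fold change of an inducing single hormone (> 1).
#' @param synergy_factor dual delta multiplier for synergistic genes (> 1).
#' @param antagonism_residual fraction of the single delta kept in dual for
#'   antagonized genes (in [0, 1)).
#' @param chrom,genome_length synthetic chromosome name and length (bp);
#'   genome_length defaults to what the cluster layout needs.
#' @param n_assisted,n_unassisted,n_inactive GR-site class counts (clusters
#'   total their sum).
#' @param units_per_cluster_range integer pair, inclusive.
#' @param cluster_span bp spanned by a cluster's units (<= 25,000).
#' @param cluster_spacing distance between cluster centers, bp.
#' @param unit_length DNase unit length, bp.
#' @param motif_strength_strong,motif_strength_weak target log-odds of
#'   planted GRE instances (defaults: consensus - 1 and consensus - 4.5).
#' @param cre_in_focal_fraction fraction of assisted sites whose focal unit
#'   also carries a CRE (the rest carry it only in a sibling unit).
#' @param peak_enrichment peak height as fold over background.
#' @param assisted_cort_fraction fractional GR peak height at assisted sites
#'   under corticosterone alone (full height needs the dual treatment).
#' @param background_rate Poisson background, tags/bp.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       replicates = 3,
                       n_per_class = c(null = 1000, gluc_only = 100,
                                       cort_only = 100, additive = 100,
                                       synergistic = 100,
                                       antag_by_cort = 100,
                                       antag_by_gluc = 100),
                       baseline_mean = 100,
                       dispersion = 0.05,
                       effect_single = 3,
                       synergy_factor = 1.5,
                       antagonism_residual = 0.1,
                       chrom = "chrS",
                       genome_length = NULL,
                       n_assisted = 50, n_unassisted = 50, n_inactive = 50,
                       units_per_cluster_range = c(2, 6),
                       cluster_span = 8000,
                       cluster_spacing = 26000,
                       unit_length = 400,
                       motif_strength_strong = NULL,
                       motif_strength_weak = NULL,
                       cre_in_focal_fraction = 0.5,
                       peak_enrichment = 5,
                       assisted_cort_fraction = 0.3,
                       background_rate = 0.05) {
  stopifnot(replicates >= 2, all(n_per_class >= 0), baseline_mean > 0,
            dispersion > 0, effect_single >= 1, synergy_factor > 1,
            antagonism_residual >= 0, antagonism_residual < 1,
            cluster_span <= 25000, unit_length > 0,
            units_per_cluster_range[1] >= 1,
            units_per_cluster_range[1] <= units_per_cluster_range[2],
            peak_enrichment > 0, background_rate > 0,
            assisted_cort_fraction >= 0, assisted_cort_fraction <= 1)
  n_clusters <- n_assisted + n_unassisted + n_inactive
  if (is.null(genome_length)) {
    genome_length <- 30000 + n_clusters * cluster_spacing
  }
  # packing feasibility: all units plus 1 gap unit each must fit in the span
  if (units_per_cluster_range[2] * 2 * unit_length > cluster_span) {
    stop("sim_config: infeasible packing - cluster_span too small for ",
         "units_per_cluster_range x unit_length")
  }
  structure(list(seed = seed, replicates = replicates,
                 n_per_class = n_per_class, baseline_mean = baseline_mean,
                 dispersion = dispersion, effect_single = effect_single,
                 synergy_factor = synergy_factor,
                 antagonism_residual = antagonism_residual,
                 chrom = chrom, genome_length = genome_length,
                 n_assisted = n_assisted, n_unassisted = n_unassisted,
                 n_inactive = n_inactive, n_clusters = n_clusters,
                 units_per_cluster_range = units_per_cluster_range,
                 cluster_span = cluster_span,
                 cluster_spacing = cluster_spacing,
                 unit_length = unit_length,
                 motif_strength_strong = motif_strength_strong,
                 motif_strength_weak = motif_strength_weak,
                 cre_in_focal_fraction = cre_in_focal_fraction,
                 peak_enrichment = peak_enrichment,
                 assisted_cort_fraction = assisted_cort_fraction,
                 background_rate = background_rate),
            class = "sim_config")
}

#' Read / write a simulation config as YAML
#' @param config a \code{sim_config}.
#' @param path file path.
#' @rdname sim_config_io
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$n_per_class <- as.list(x$n_per_class) # keep class names in the YAML map
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname sim_config_io
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$n_per_class <- unlist(x$n_per_class)
  x$n_clusters <- NULL
  gl <- x$genome_length
  x$genome_length <- NULL
  cfg <- do.call(sim_config, x)
  if (!is.null(gl)) cfg$genome_length <- gl
  cfg
}

#' Expected condition means per interaction class
#'
#' The deterministic mean table behind the count simulator; exposed so the
#' class formulas can be inspected and tested directly.
#'
#' @param config a \code{sim_config}.
#' @return matrix class x condition (nt, gluc, cort, dual) of expected
#'   counts.
#' @export
class_condition_means <- function(config) {
  mu0 <- config$baseline_mean
  eff <- config$effect_single
  delta <- mu0 * (eff - 1)
  syn <- config$synergy_factor
  res <- config$antagonism_residual
  m <- rbind(
    null = c(mu0, mu0, mu0, mu0),
    gluc_only = c(mu0, mu0 * eff, mu0, mu0 * eff),
    cort_only = c(mu0, mu0, mu0 * eff, mu0 * eff),
    additive = c(mu0, mu0 * eff, mu0 * eff, mu0 + 2 * delta),
    synergistic = c(mu0, mu0 * eff, mu0 * eff, mu0 + syn * 2 * delta),
    antag_by_cort = c(mu0, mu0 * eff, mu0, mu0 + res * delta),
    antag_by_gluc = c(mu0, mu0, mu0 * eff, mu0 + res * delta)
  )
  colnames(m) <- c("nt", "gluc", "cort", "dual")
  if (any(m <= 0)) stop("class_condition_means: non-positive expected mean")
  m
}

#' Simulate a four-condition count matrix with planted interaction classes
#'
#' @param config a \code{sim_config}.
#' @return list with \code{counts} (a \code{count_matrix} with feature
#'   lengths) and \code{truth} (data.frame gene id, class, plus the four
#'   expected means).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mu_table <- class_condition_means(config)
  classes <- rep(names(config$n_per_class), config$n_per_class)
  n <- length(classes)
  if (n == 0) stop("simulate_counts: no genes configured")
  ids <- sprintf("gene_%05d", seq_len(n))
  conds <- c("nt", "gluc", "cort", "dual")
  reps <- config$replicates
  samples <- as.vector(outer(conds, seq_len(reps),
                             function(c, r) paste0(c, "_rep", r)))
  condition_map <- rep(conds, times = reps)
  names(condition_map) <- samples
  set.seed(derive_seed(config$seed, "counts"))
  lengths <- sample(500:3000, n, replace = TRUE)
  names(lengths) <- ids
  mu <- mu_table[classes, , drop = FALSE] # n x 4
  m <- matrix(0L, nrow = n, ncol = length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    m[, j] <- stats::rnbinom(n, mu = mu[, condition_map[j]],
                             size = 1 / config$dispersion)
  }
  truth <- data.frame(id = ids, class = classes,
                      mu_nt = mu[, "nt"], mu_gluc = mu[, "gluc"],
                      mu_cort = mu[, "cort"], mu_dual = mu[, "dual"],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(counts = count_matrix(m, condition_map, feature_lengths = lengths),
       truth = truth)
}

#' Built-in GRE and CRE position weight matrices
#'
#' A 15 bp glucocorticoid response element (AGAACAnnnTGTTCT-like inverted
#' repeat with an uninformative 3 bp spacer) and a 12 bp full-site cAMP
#' response element (the TGACGTCA palindrome with flanking preference).
#' Columns have heterogeneous probabilities (0.85 / 0.09 / 0.03 / 0.03) so
#' consensus degradation can approach a target log-odds in moderate steps.
#'
#' @return a \code{pwm}.
#' @rdname builtin_pwms
#' @export
gre_pwm <- function() {
  consensus_pwm("AGAACAGAATGTTCT", "gre", spacer = 7:9)
}

#' @rdname builtin_pwms
#' @export
cre_pwm <- function() {
  consensus_pwm("ATTGACGTCAAT", "cre")
}

# Heterogeneous-column PWM from a consensus string; spacer positions are
# uniform. Second-best base gets 0.09 so degradation steps are ~2.2 nats.
consensus_pwm <- function(consensus, name, spacer = integer(0)) {
  cons <- strsplit(consensus, "")[[1]]
  probs <- sapply(seq_along(cons), function(i) {
    if (i %in% spacer) return(rep(0.25, 4))
    p <- rep(0.03, 4)
    names(p) <- c("A", "C", "G", "T")
    p[cons[i]] <- 0.85
    second <- setdiff(c("A", "C", "G", "T"), cons[i])[1]
    p[second] <- 0.09
    unname(p / sum(p))
  })
  pwm(probs, name = name)
}

#' Degrade a PWM consensus toward a target log-odds
#'
#' Starting from the consensus sequence, repeatedly substitutes the single
#' base change that keeps the score highest, until the score is at or below
#' the target. This is the generator's knob for planting weaker motif
#' instances.
#'
#' @param motif a \code{pwm}.
#' @param target target log-odds score.
#' @return list with \code{seq} and its exact \code{score}.
#' @export
degrade_consensus <- function(motif, target) {
  lo <- motif$logodds
  bases <- c("A", "C", "G", "T")
  codes <- apply(lo, 2, which.max)
  score <- sum(lo[cbind(codes, seq_along(codes))])
  while (score > target) {
    best <- NULL
    for (pos in seq_along(codes)) {
      for (b in seq_len(4)) {
        if (b == codes[pos]) next
        s2 <- score - lo[codes[pos], pos] + lo[b, pos]
        if (s2 < score && (is.null(best) || s2 > best$score)) {
          best <- list(pos = pos, b = b, score = s2)
        }
      }
    }
    if (is.null(best)) break
    codes[best$pos] <- best$b
    score <- best$score
  }
  list(seq = paste(bases[codes], collapse = ""), score = score)
}

#' Simulate a synthetic genome with enhancer clusters and planted motifs
#'
#' Lays out \code{n_clusters} enhancer clusters along one synthetic
#' chromosome (regular spacing), each with 2+ non-overlapping DNase units.
#' One unit per cluster hosts the GR binding site. Assisted sites get a
#' planted weak GRE plus at least one CRE in the focal and/or a sibling
#' unit; unassisted sites get a strong GRE and no CRE; inactive sites get no
#' motif. CTCF intervals flank the cluster edges only; each cluster has one
#' flanking gene TSS (assisted clusters next to synergistic genes,
#' unassisted next to cort-induced genes, inactive next to null genes).
#'
#' @param config a \code{sim_config}.
#' @return list of class \code{sim_genome}: \code{sequence} (named list of
#'   chromosome strings), \code{annotation} (interval data.frames:
#'   \code{tss}, \code{dhs}, \code{grbs}, \code{ctcf}), \code{truth} (lists:
#'   \code{site_class}, \code{cluster_membership}, \code{planted_motifs},
#'   \code{gene_class}), and the \code{pwms} used.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  gre <- gre_pwm()
  cre <- cre_pwm()
  cons_gre <- consensus_score(gre)
  strong_target <- config$motif_strength_strong %||% (cons_gre - 1)
  weak_target <- config$motif_strength_weak %||% (cons_gre - 4.5)
  strong <- degrade_consensus(gre, strong_target)
  weak <- degrade_consensus(gre, weak_target)
  if (weak$score >= strong$score) {
    stop("simulate_genome: weak GRE target must be below the strong target")
  }
  cre_seq <- consensus_seq(cre)
  L <- config$genome_length
  bases <- sample.int(4, L, replace = TRUE)
  seq_raw <- charToRaw(intToUtf8(c(65L, 67L, 71L, 84L)[bases]))
  plant <- function(seq_string, start0) { # returns planted interval rows
    s <- charToRaw(seq_string)
    seq_raw[(start0 + 1):(start0 + length(s))] <<- s
    c(start0, start0 + length(s))
  }
  n_cl <- config$n_clusters
  site_classes <- sample(rep(c("assisted", "unassisted", "inactive"),
                             c(config$n_assisted, config$n_unassisted,
                               config$n_inactive)))
  span <- config$cluster_span
  ul <- config$unit_length
  tss <- list(); dhs <- list(); grbs <- list(); ctcf <- list()
  motifs <- list(); gene_class <- character(); cluster_membership <- character()
  pick <- function(v) if (length(v) == 1L) v else sample(v, 1) # no 1:n trap
  for (i in seq_len(n_cl)) {
    center <- 15000 + (i - 1) * config$cluster_spacing
    k <- pick(config$units_per_cluster_range[1]:
                config$units_per_cluster_range[2])
    slot <- span / k
    jitter_max <- max(floor(slot - ul), 1)
    starts <- floor(center - span / 2 + (seq_len(k) - 1) * slot +
                      sample.int(jitter_max, k, replace = TRUE) - 1)
    units <- data.frame(chrom = config$chrom, start = starts,
                        end = starts + ul,
                        name = sprintf("dhs_%03d_%d", i, seq_len(k)),
                        score = 0, strand = ".", stringsAsFactors = FALSE)
    focal <- pick(seq_len(k))
    fcenter <- interval_center(units[focal, , drop = FALSE])
    site_id <- sprintf("site_%03d", i)
    cls <- site_classes[i]
    grbs[[i]] <- data.frame(chrom = config$chrom,
                            start = units$start[focal],
                            end = units$end[focal],
                            name = site_id, score = 0, strand = ".",
                            stringsAsFactors = FALSE)
    cluster_membership[site_id] <- sprintf("cluster_%03d", i)
    if (cls == "assisted") {
      iv <- plant(weak$seq, fcenter - nchar(weak$seq) %/% 2)
      motifs[[length(motifs) + 1]] <- data.frame(
        chrom = config$chrom, start = iv[1], end = iv[2], pwm = "gre",
        strand = "+", logodds = weak$score, site = site_id,
        stringsAsFactors = FALSE)
      # CRE in the focal unit for a fraction of sites, plus one in a sibling
      if (stats::runif(1) < config$cre_in_focal_fraction) {
        off <- pick(30:(ul %/% 2 - 10))
        iv <- plant(cre_seq, fcenter + off)
        motifs[[length(motifs) + 1]] <- data.frame(
          chrom = config$chrom, start = iv[1], end = iv[2], pwm = "cre",
          strand = "+", logodds = consensus_score(cre), site = site_id,
          stringsAsFactors = FALSE)
      }
      sib <- if (k > 1) pick(setdiff(seq_len(k), focal)) else focal
      scenter <- interval_center(units[sib, , drop = FALSE])
      pos <- if (sib == focal) scenter - ul %/% 2 + 10 else
        scenter - nchar(cre_seq) %/% 2
      iv <- plant(cre_seq, pos)
      motifs[[length(motifs) + 1]] <- data.frame(
        chrom = config$chrom, start = iv[1], end = iv[2], pwm = "cre",
        strand = "+", logodds = consensus_score(cre), site = site_id,
        stringsAsFactors = FALSE)
    } else if (cls == "unassisted") {
      iv <- plant(strong$seq, fcenter - nchar(strong$seq) %/% 2)
      motifs[[length(motifs) + 1]] <- data.frame(
        chrom = config$chrom, start = iv[1], end = iv[2], pwm = "gre",
        strand = "+", logodds = strong$score, site = site_id,
        stringsAsFactors = FALSE)
    }
    dhs[[i]] <- units
    ctcf[[i]] <- data.frame(chrom = config$chrom,
                            start = c(center - span / 2 - 1100,
                                      center + span / 2 + 900),
                            end = c(center - span / 2 - 900,
                                    center + span / 2 + 1100),
                            name = sprintf("ctcf_%03d_%s", i, c("L", "R")),
                            score = 0, strand = ".",
                            stringsAsFactors = FALSE)
    gene_id <- sprintf("gene_cl_%03d", i)
    gstrand <- if (i %% 2 == 0) "-" else "+"
    gpos <- if (gstrand == "+") center + span / 2 + 2000 else
      center - span / 2 - 2000
    tss[[i]] <- data.frame(chrom = config$chrom, start = gpos,
                           end = gpos + 1, name = gene_id, score = 0,
                           strand = gstrand, stringsAsFactors = FALSE)
    gene_class[gene_id] <- switch(cls, assisted = "synergistic",
                                  unassisted = "cort_only", "null")
  }
  site_class <- site_classes
  names(site_class) <- sprintf("site_%03d", seq_len(n_cl))
  motifs <- do.call(rbind, motifs)
  if (any(motifs$start < 0) || any(motifs$end > L)) {
    stop("simulate_genome: planted motif outside genome bounds")
  }
  sequence <- list(rawToChar(seq_raw))
  names(sequence) <- config$chrom
  structure(list(
    sequence = sequence,
    annotation = list(tss = do.call(rbind, tss), dhs = do.call(rbind, dhs),
                      grbs = do.call(rbind, grbs),
                      ctcf = do.call(rbind, ctcf)),
    truth = list(site_class = site_class,
                 cluster_membership = cluster_membership,
                 planted_motifs = motifs, gene_class = gene_class),
    pwms = list(gre = gre, cre = cre),
    config = config
  ), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %s (%s bp), %d clusters (%s)\n",
              x$config$chrom, format(x$config$genome_length, big.mark = ","),
              x$config$n_clusters,
              paste(sprintf("%s %d", names(table(x$truth$site_class)),
                            table(x$truth$site_class)), collapse = ", ")))
  invisible(x)
}

# Expected peak plan for one (assay, condition): data.frame center, height
# (tags/bp at the apex), halfwidth. Heights are multiples of
# peak_enrichment * background_rate.
coverage_plan <- function(sim, condition, assay) {
  cfg <- sim$config
  h1 <- cfg$peak_enrichment * cfg$background_rate
  truth <- sim$truth
  plan <- data.frame(center = numeric(0), height = numeric(0),
                     halfwidth = numeric(0))
  add <- function(centers, height, halfwidth) {
    if (length(centers) && height > 0) {
      plan <<- rbind(plan, data.frame(center = centers, height = height,
                                      halfwidth = halfwidth))
    }
  }
  grbs_centers <- interval_center(sim$annotation$grbs)
  names(grbs_centers) <- sim$annotation$grbs$name
  site_cls <- truth$site_class[sim$annotation$grbs$name]
  dhs_centers <- interval_center(sim$annotation$dhs)
  cluster_of_unit <- sub("^dhs_([0-9]+)_.*$", "\\1", sim$annotation$dhs$name)
  assisted_clusters <- sub("^site_", "", names(site_cls)[site_cls == "assisted"])
  unit_in_assisted <- cluster_of_unit %in% assisted_clusters
  if (assay == "GR") {
    ua <- grbs_centers[site_cls == "unassisted"]
    as <- grbs_centers[site_cls == "assisted"]
    if (condition %in% c("cort", "dual")) add(ua, h1, 200)
    if (condition == "cort") add(as, h1 * cfg$assisted_cort_fraction, 200)
    if (condition == "dual") add(as, h1, 200)
  } else if (assay == "CREB") {
    cre <- truth$planted_motifs[truth$planted_motifs$pwm == "cre", ,
                                drop = FALSE]
    if (condition %in% c("gluc", "dual") && nrow(cre)) {
      add(floor((cre$start + cre$end) / 2), h1, 200)
    }
  } else if (assay == "H3K27ac") {
    add(dhs_centers, h1 * 0.5, 600) # basal enhancer signal everywhere
    if (condition == "gluc") add(dhs_centers[unit_in_assisted], h1 * 0.75, 600)
    if (condition == "dual") add(dhs_centers[unit_in_assisted], h1 * 1.25, 600)
  } else if (assay == "DNase") {
    add(dhs_centers, h1, 200)
  } else {
    stop("simulate_coverage: unknown assay '", assay, "'")
  }
  plan
}

#' Simulate a condition- and assay-specific coverage track
#'
#' Poisson tags at \code{background_rate} per base, plus triangular peaks
#' per the assay rule table: GR binds unassisted sites equally in cort and
#' dual, assisted sites weakly in cort and fully only in dual, and nowhere
#' in nt/gluc; CREB binds CRE-bearing units in gluc and dual; H3K27ac is
#' basally present at all units, elevated across assisted-cluster units in
#' gluc and further in dual; DNase marks all units in all conditions. Each
#' (assay, condition, replicate) triple has its own RNG stream derived from
#' the master seed.
#'
#' @param sim a \code{sim_genome}.
#' @param condition one of nt, gluc, cort, dual.
#' @param assay one of GR, CREB, H3K27ac, DNase.
#' @param replicate replicate index.
#' @return a \code{coverage_track}.
#' @export
simulate_coverage <- function(sim, condition, assay, replicate = 1) {
  stopifnot(inherits(sim, "sim_genome"))
  if (!condition %in% c("nt", "gluc", "cort", "dual")) {
    stop("simulate_coverage: unknown condition '", condition, "'")
  }
  cfg <- sim$config
  plan <- coverage_plan(sim, condition, assay)
  L <- cfg$genome_length
  lambda <- rep(cfg$background_rate, L)
  for (r in seq_len(nrow(plan))) {
    hw <- plan$halfwidth[r]
    c0 <- plan$center[r]
    lo <- max(c0 - hw, 0); hi <- min(c0 + hw, L - 1)
    x <- lo:hi
    lambda[x + 1] <- lambda[x + 1] +
      plan$height[r] * pmax(0, 1 - abs(x - c0) / hw)
  }
  set.seed(derive_seed(cfg$seed,
                       paste(assay, condition, replicate, sep = "|")))
  v <- stats::rpois(L, lambda)
  vals <- list(as.numeric(v))
  names(vals) <- cfg$chrom
  coverage_track(vals)
}

#' Site-by-sample window counts straight from the simulator
#'
#' Generates each (condition, replicate) track in turn, quantifies tags at
#' the given sites, and discards the track, so memory stays flat.
#'
#' @param sim a \code{sim_genome}.
#' @param sites interval data.frame (defaults to the simulated GR sites).
#' @param assay assay label.
#' @param conditions conditions to simulate.
#' @param halfwidth quantification half-window, bp.
#' @return a \code{count_matrix} with \code{lib_sizes} attribute.
#' @export
simulate_site_counts <- function(sim, sites = NULL, assay = "GR",
                                 conditions = c("nt", "gluc", "cort", "dual"),
                                 halfwidth = 200) {
  sites <- sites %||% sim$annotation$grbs
  reps <- sim$config$replicates
  cols <- list(); lib <- numeric(0); cond_map <- character(0)
  for (cc in conditions) {
    for (r in seq_len(reps)) {
      tr <- simulate_coverage(sim, cc, assay, r)
      nm <- paste0(cc, "_rep", r)
      cols[[nm]] <- round(quantify_tags(sites, tr, halfwidth))
      lib[nm] <- tr$total_tags
      cond_map[nm] <- cc
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- if (all(sites$name != ".")) sites$name else
    sprintf("site_%d", seq_len(nrow(sites)))
  cm <- count_matrix(m, cond_map)
  attr(cm, "lib_sizes") <- lib
  cm
}

#' Write a full simulation to disk
#'
#' Counts as TSV, annotation as BED6, ground truth as TSV, config as YAML,
#' and (optionally) coverage as bedGraph.
#'
#' @param sim_counts result of [simulate_counts()] (or NULL to skip).
#' @param sim_genome_obj result of [simulate_genome()] (or NULL to skip).
#' @param outdir output directory (created if needed).
#' @param tracks optional named list of \code{coverage_track} to write as
#'   bedGraph.
#' @return the output directory, invisibly.
#' @export
write_simulation <- function(sim_counts = NULL, sim_genome_obj = NULL,
                             outdir, tracks = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim_counts)) {
    write_counts(sim_counts$counts, file.path(outdir, "counts.tsv"))
    utils::write.table(sim_counts$truth,
                       file.path(outdir, "gene_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim_genome_obj)) {
    ann <- sim_genome_obj$annotation
    for (nm in names(ann)) {
      write_bed(ann[[nm]], file.path(outdir, paste0(nm, ".bed")))
    }
    truth <- sim_genome_obj$truth
    utils::write.table(
      data.frame(id = names(truth$site_class), class = truth$site_class,
                 cluster = truth$cluster_membership[names(truth$site_class)]),
      file.path(outdir, "site_truth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$planted_motifs,
                       file.path(outdir, "planted_motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_pwm(sim_genome_obj$pwms, file.path(outdir, "motifs.txt"))
    write_sim_config(sim_genome_obj$config, file.path(outdir, "config.yaml"))
  }
  if (!is.null(tracks)) {
    for (nm in names(tracks)) {
      write_bedgraph(tracks[[nm]], file.path(outdir, paste0(nm, ".bedGraph")))
    }
  }
  invisible(outdir)
}
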