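#' Configuration for the forward-in-time SSR population simulator
#'
#' Parameterises a Wright-Fisher metapopulation of diploid, partially
#' selfing individuals arranged in island-model demes (optionally two
#' hierarchical groups of demes with distinct within- and between-group
#' migration rates), genotyped at map-placed microsatellite loci mutating
#' under a stepwise (SMM) or two-phase (TPM) model. Divergent selection can
#' be planted at chosen loci.
#'
#' @param seed Integer RNG seed; every run is fully reproducible from it.
#' @param n_demes Number of demes.
#' @param deme_size Diploid individuals per deme (constant).
#' @param n_groups Number of deme groups (1 = plain island model). Demes are
#'   split as evenly as possible across groups.
#' @param migration_rate Per-generation probability that an offspring's
#'   parents are drawn from another deme (single-group model).
#' @param migration_within,migration_between Hierarchical migration rates
#'   (used when `n_groups > 1`): probability the source deme is another deme
#'   of the same group / of a different group.
#' @param selfing_rate Probability an individual self-fertilises.
#' @param n_generations Generations to run forward.
#' @param n_loci Number of SSR loci.
#' @param n_linkage_groups Linkage groups; loci are spread round-robin with
#'   uniform positions on a 0-100 cM scale, then ordered.
#' @param mutation_model `"SMM"` or `"TPM"`.
#' @param mutation_rate Per allele copy per generation.
#' @param p_smm TPM single-step probability (ignored under SMM).
#' @param tpm_variance Variance of the TPM multi-step geometric jump.
#' @param founder_k Distinct founder alleles per locus.
#' @param founder_concentration Dirichlet concentration for founder allele
#'   frequencies (1 = uniform simplex).
#' @param sweeps Optional tibble/data.frame with columns `locus` (index or
#'   name), `group` (group index under selection), `start_gen`, `s`
#'   (selection coefficient). From `start_gen` on, a then-segregating
#'   minor allele of the target group confers fitness `(1+s)^dosage`
#'   inside that group, sweeping it towards fixation there while it stays
#'   rare elsewhere.
#' @param sample_sizes Individuals sampled per deme at the end (scalar or
#'   vector of length `n_demes`).
#' @param missing_rate Per-cell missing-data probability applied at sampling.
#' @param null_allele_rate Per-copy per-generation mutation rate to the null
#'   (non-amplifying) allele state.
#' @param split_gen Generation from which between-group migration ceases
#'   (`Inf` = never), emulating a shared base collection that later splits
#'   into isolated breeding pools.
#' @param track_pedigree Record the full pedigree kinship matrix of sampled
#'   individuals (quadratic cost; off by default).
#' @param fst_every Record the realized multilocus G\\_ST every this many
#'   generations.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_demes = 2L,
                       deme_size = 100L,
                       n_groups = 1L,
                       migration_rate = 0.01,
                       migration_within = migration_rate,
                       migration_between = migration_rate / 10,
                       selfing_rate = 0.95,
                       n_generations = 150L,
                       n_loci = 100L,
                       n_linkage_groups = 15L,
                       mutation_model = c("SMM", "TPM"),
                       mutation_rate = 1e-3,
                       p_smm = 0.7,
                       tpm_variance = 30,
                       founder_k = 5L,
                       founder_concentration = 1,
                       sweeps = NULL,
                       split_gen = Inf,
                       sample_sizes = deme_size,
                       missing_rate = 0,
                       null_allele_rate = 0,
                       track_pedigree = FALSE,
                       fst_every = 10L) {
  mutation_model <- match.arg(mutation_model)
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
      stop("invalid config field `", nm, "`: must be in [0, 1]", call. = FALSE)
    }
  }
  chk01(migration_rate, "migration_rate")
  chk01(migration_within, "migration_within")
  chk01(migration_between, "migration_between")
  chk01(selfing_rate, "selfing_rate")
  chk01(missing_rate, "missing_rate")
  chk01(null_allele_rate, "null_allele_rate")
  chk01(mutation_rate, "mutation_rate")
  chk01(p_smm, "p_smm")
  if (n_demes < 1 || deme_size < 2) stop("invalid config field `n_demes`/`deme_size`", call. = FALSE)
  if (n_groups < 1 || n_groups > n_demes) stop("invalid config field `n_groups`", call. = FALSE)
  if (founder_k < 1) stop("invalid config field `founder_k`", call. = FALSE)
  sample_sizes <- rep_len(as.integer(sample_sizes), n_demes)
  if (any(sample_sizes > deme_size)) {
    stop("invalid config field `sample_sizes`: larger than deme_size", call. = FALSE)
  }
  if (!is.null(sweeps)) {
    sweeps <- tibble::as_tibble(sweeps)
    need <- c("locus", "group", "start_gen", "s")
    if (!all(need %in% names(sweeps))) {
      stop("invalid config field `sweeps`: needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (any(sweeps$group > n_groups)) {
      stop("invalid config field `sweeps`: group index out of range", call. = FALSE)
    }
    if (is.numeric(sweeps$locus) && any(sweeps$locus > n_loci)) {
      stop("invalid config field `sweeps`: locus index exceeds n_loci", call. = FALSE)
    }
  }
  structure(list(
    seed = as.integer(seed), n_demes = as.integer(n_demes),
    deme_size = as.integer(deme_size), n_groups = as.integer(n_groups),
    migration_rate = migration_rate, migration_within = migration_within,
    migration_between = migration_between, selfing_rate = selfing_rate,
    n_generations = as.integer(n_generations), n_loci = as.integer(n_loci),
    n_linkage_groups = as.integer(n_linkage_groups),
    mutation_model = mutation_model, mutation_rate = mutation_rate,
    p_smm = p_smm, tpm_variance = tpm_variance,
    founder_k = as.integer(founder_k),
    founder_concentration = founder_concentration,
    sweeps = sweeps, split_gen = split_gen, sample_sizes = sample_sizes,
    missing_rate = missing_rate, null_allele_rate = null_allele_rate,
    track_pedigree = isTRUE(track_pedigree), fst_every = as.integer(fst_every)
  ), class = "sim_config")
}

# internal null-allele state sentinel (output bp code is 0)
.NULL_STATE <- -999L

# sample() without its scalar-first-argument surprise
.resample <- function(x, n, replace = TRUE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}

.rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  g / sum(g)
}

# multilocus Nei G_ST from the full deme haplotype matrices
.truth_gst <- function(A1, A2, deme, n_demes) {
  ht_num <- 0; hs_num <- 0; nl <- 0
  for (j in seq_len(ncol(A1))) {
    alleles <- c(A1[, j], A2[, j])
    demes2 <- c(deme, deme)
    tab <- table(demes2, alleles)
    pmat <- tab / rowSums(tab)
    hs <- mean(1 - rowSums(pmat^2))
    pbar <- colSums(tab) / sum(tab)
    ht <- 1 - sum(pbar^2)
    if (ht > 0) {
      ht_num <- ht_num + ht
      hs_num <- hs_num + hs
      nl <- nl + 1
    }
  }
  if (nl == 0) return(NA_real_)
  (ht_num - hs_num) / ht_num
}

#' Simulate a structured, selfing SSR-genotyped population
#'
#' Runs the forward Wright-Fisher simulation described in [sim_config()]:
#' non-overlapping generations, island (or hierarchical island) migration of
#' parent choice, partial selfing, recombination along the linkage map with
#' the Haldane map function (no interference), stepwise/two-phase SSR
#' mutation plus optional null-allele mutation, and optional planted
#' divergent selection. Internal allele states are repeat scores; sampled
#' output is converted to fragment sizes in bp (`100 + 2 * state`).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_result` with elements `genotypes` (a
#'   [geno_matrix()] with deme labels), `map` (marker/linkage_group/cM
#'   tibble), `grouping` (tibble `individual`, `deme`, `group`) and `truth`
#'   (realized allele counts, G\\_ST trajectory, sweep status, founder and
#'   mutant allele registry, optional pedigree kinship of sampled
#'   individuals).
#' @examples
#' res <- simulate_ssr(sim_config(seed = 1, n_loci = 10, n_generations = 20,
#'                                deme_size = 30))
#' res$genotypes
#' @export
simulate_ssr <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  D <- cfg$n_demes
  N <- cfg$deme_size
  Ntot <- D * N
  deme_of <- rep(seq_len(D), each = N)
  group_of_deme <- rep(seq_len(cfg$n_groups), length.out = D)
  group_of_deme <- sort(group_of_deme)

  # map: loci round-robin over linkage groups, uniform cM in [0, 100]
  lg <- rep(seq_len(cfg$n_linkage_groups), length.out = L)
  pos <- stats::runif(L, 0, 100)
  ord <- order(lg, pos)
  lg <- lg[ord]; pos <- pos[ord]
  locus_names <- sprintf("L%03d", seq_len(L))
  map <- tibble::tibble(marker = locus_names,
                        linkage_group = paste0("LG", lg),
                        cM = round(pos, 3))
  # Haldane recombination fraction between adjacent loci; free recombination
  # (0.5) at linkage-group boundaries and for the leading locus
  rfrac <- rep(0.5, L)
  if (L > 1) {
    same <- lg[-1] == lg[-L]
    d <- pos[-1] - pos[-L]
    rfrac[-1] <- ifelse(same, 0.5 * (1 - exp(-2 * d / 100)), 0.5)
  }

  # founder alleles: distinct repeat scores, Dirichlet frequencies
  founder_states <- vector("list", L)
  A1 <- matrix(0L, Ntot, L)
  A2 <- matrix(0L, Ntot, L)
  allele_registry <- vector("list", L)
  for (j in seq_len(L)) {
    st <- sort(sample(10:60, cfg$founder_k))
    fr <- .rdirichlet1(cfg$founder_k, cfg$founder_concentration)
    A1[, j] <- .resample(st, Ntot, prob = fr)
    A2[, j] <- .resample(st, Ntot, prob = fr)
    founder_states[[j]] <- st
    allele_registry[[j]] <- st
  }

  sweeps <- cfg$sweeps
  if (!is.null(sweeps) && is.character(sweeps$locus)) {
    sweeps$locus <- match(sweeps$locus, locus_names)
  }
  sweep_allele <- rep(NA_integer_, if (is.null(sweeps)) 0 else nrow(sweeps))

  tpm_geom_p <- {
    # geometric jump magnitude with the requested variance
    v <- cfg$tpm_variance
    (sqrt(1 + 4 * v) - 1) / (2 * v)
  }

  K <- NULL
  if (cfg$track_pedigree) {
    K <- diag(0.5, Ntot)  # founders unrelated, non-inbred: f_ii = 1/2
  }

  fst_traj <- list()
  record_fst <- function(gen) {
    tibble::tibble(generation = gen,
                   gst = .truth_gst(A1, A2, deme_of, D))
  }
  if (D > 1) fst_traj[[1]] <- record_fst(0L)

  draw_steps <- function(n) {
    if (cfg$mutation_model == "SMM") {
      sample(c(-1L, 1L), n, replace = TRUE)
    } else {
      mag <- ifelse(stats::runif(n) < cfg$p_smm, 1L,
                    stats::rgeom(n, tpm_geom_p) + 1L)
      mag * sample(c(-1L, 1L), n, replace = TRUE)
    }
  }

  for (gen in seq_len(cfg$n_generations)) {
    # selection weights per individual (per deme-group), from active sweeps
    w <- rep(1, Ntot)
    if (!is.null(sweeps)) {
      for (si in seq_len(nrow(sweeps))) {
        if (gen < sweeps$start_gen[si]) next
        jl <- sweeps$locus[si]
        target <- which(group_of_deme[deme_of] == sweeps$group[si])
        if (is.na(sweep_allele[si])) {
          # favor an allele segregating at intermediate frequency in the
          # target group but rare outside it: divergent selection then
          # builds a strong between-group contrast without collapsing the
          # group's effective size
          alle_t <- c(A1[target, jl], A2[target, jl])
          alle_t <- alle_t[alle_t != .NULL_STATE]
          alle_o <- c(A1[-target, jl], A2[-target, jl])
          tab_t <- table(alle_t) / length(alle_t)
          cand <- names(tab_t)[tab_t >= 0.15 & tab_t <= 0.6]
          if (!length(cand)) cand <- names(tab_t)[tab_t <= 0.6]
          if (!length(cand)) cand <- names(tab_t)
          freq_o <- vapply(cand, function(a) {
            mean(alle_o == as.integer(a))
          }, numeric(1))
          sweep_allele[si] <- as.integer(cand[which.min(freq_o)])
        }
        dosage <- (A1[, jl] == sweep_allele[si]) + (A2[, jl] == sweep_allele[si])
        w[target] <- w[target] * (1 + sweeps$s[si])^dosage[target]
      }
    }

    # source deme of each offspring (island or hierarchical island)
    src <- integer(Ntot)
    for (d in seq_len(D)) {
      idx <- which(deme_of == d)
      g <- group_of_deme[d]
      same_g <- setdiff(which(group_of_deme == g), d)
      other_g <- which(group_of_deme != g)
      if (cfg$n_groups == 1) {
        mw <- if (length(same_g)) cfg$migration_rate else 0
        mb <- 0
      } else {
        mw <- if (length(same_g)) cfg$migration_within else 0
        mb <- if (length(other_g) && gen < cfg$split_gen) cfg$migration_between else 0
      }
      u <- stats::runif(length(idx))
      s_d <- rep(d, length(idx))
      mig_w <- u < mw
      mig_b <- !mig_w & u < mw + mb
      if (any(mig_w)) s_d[mig_w] <- .resample(same_g, sum(mig_w))
      if (any(mig_b)) s_d[mig_b] <- .resample(other_g, sum(mig_b))
      src[idx] <- s_d
    }

    # parents within source demes, fitness-weighted
    mothers <- integer(Ntot); fathers <- integer(Ntot)
    for (d in seq_len(D)) {
      off <- which(src == d)
      if (!length(off)) next
      pool <- which(deme_of == d)
      pw <- w[pool]
      mothers[off] <- pool[sample.int(length(pool), length(off), replace = TRUE, prob = pw)]
      fathers[off] <- pool[sample.int(length(pool), length(off), replace = TRUE, prob = pw)]
    }
    selfed <- stats::runif(Ntot) < cfg$selfing_rate
    fathers[selfed] <- mothers[selfed]

    gam1 <- .make_gametes(A1, A2, mothers, rfrac)
    gam2 <- .make_gametes(A1, A2, fathers, rfrac)

    # SSR mutation (null copies are absorbing), then null-allele mutation
    for (gam_name in c("gam1", "gam2")) {
      g <- get(gam_name)
      hit <- which(stats::runif(length(g)) < cfg$mutation_rate & g != .NULL_STATE)
      if (length(hit)) {
        g[hit] <- g[hit] + draw_steps(length(hit))
        jcol <- ((hit - 1L) %/% Ntot) + 1L
        for (j in unique(jcol)) {
          allele_registry[[j]] <- union(allele_registry[[j]], g[hit[jcol == j]])
        }
      }
      if (cfg$null_allele_rate > 0) {
        nh <- which(stats::runif(length(g)) < cfg$null_allele_rate)
        if (length(nh)) {
          g[nh] <- .NULL_STATE
          jcol <- unique(((nh - 1L) %/% Ntot) + 1L)
          for (j in jcol) allele_registry[[j]] <- union(allele_registry[[j]], .NULL_STATE)
        }
      }
      assign(gam_name, g)
    }
    A1 <- gam1
    A2 <- gam2

    if (cfg$track_pedigree) {
      Km <- K[mothers, , drop = FALSE]
      Kf <- K[fathers, , drop = FALSE]
      Knew <- 0.25 * (Km[, mothers, drop = FALSE] + Km[, fathers, drop = FALSE] +
                      Kf[, mothers, drop = FALSE] + Kf[, fathers, drop = FALSE])
      diag(Knew) <- 0.5 * (1 + K[cbind(mothers, fathers)])
      K <- Knew
    }

    if (D > 1 && (gen %% cfg$fst_every == 0 || gen == cfg$n_generations)) {
      fst_traj[[length(fst_traj) + 1L]] <- record_fst(gen)
    }
  }

  # sample individuals and emit module objects
  picked <- unlist(lapply(seq_len(D), function(d) {
    pool <- which(deme_of == d)
    sort(sample(pool, cfg$sample_sizes[d]))
  }))
  deme_lab <- paste0("D", deme_of[picked])
  ids <- sprintf("D%d_i%03d", deme_of[picked],
                 stats::ave(picked, deme_of[picked], FUN = seq_along))
  to_bp <- function(st) {
    bp <- 100L + 2L * st
    bp[st == .NULL_STATE] <- 0L
    bp[bp < 2L & st != .NULL_STATE] <- 2L
    bp
  }
  s1 <- to_bp(A1[picked, , drop = FALSE])
  s2 <- to_bp(A2[picked, , drop = FALSE])
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(s1)) < cfg$missing_rate, nrow(s1))
    s1[mask] <- NA_integer_
    s2[mask] <- NA_integer_
  }
  dimnames(s1) <- dimnames(s2) <- list(ids, locus_names)
  gm <- geno_matrix(s1, s2, pop = deme_lab)

  grouping <- tibble::tibble(individual = ids,
                             deme = deme_lab,
                             group = paste0("G", group_of_deme[deme_of[picked]]))

  sweep_status <- NULL
  if (!is.null(sweeps)) {
    sweep_status <- sweeps
    sweep_status$locus_name <- locus_names[sweeps$locus]
    sweep_status$favored_state <- sweep_allele
    sweep_status$favored_bp <- 100L + 2L * sweep_allele
    freq_of <- function(jl, demes_in) {
      idx <- which(deme_of %in% demes_in)
      alle <- c(A1[idx, jl], A2[idx, jl])
      mean(alle == sweep_allele[match(jl, sweeps$locus)])
    }
    sweep_status$final_freq_target <- vapply(seq_len(nrow(sweeps)), function(si) {
      freq_of(sweeps$locus[si], which(group_of_deme == sweeps$group[si]))
    }, numeric(1))
    sweep_status$final_freq_other <- vapply(seq_len(nrow(sweeps)), function(si) {
      freq_of(sweeps$locus[si], which(group_of_deme != sweeps$group[si]))
    }, numeric(1))
  }

  truth <- list(
    realized_allele_counts = apply(rbind(s1, s2), 2, function(x) {
      length(unique(stats::na.omit(x)))
    }),
    fst_trajectory = if (length(fst_traj)) dplyr::bind_rows(fst_traj),
    founder_states = founder_states,
    allele_registry = allele_registry,
    sweep_status = sweep_status,
    kinship = if (cfg$track_pedigree) {
      Ks <- K[picked, picked]
      dimnames(Ks) <- list(ids, ids)
      Ks
    }
  )
  structure(list(genotypes = gm, map = map, grouping = grouping,
                 truth = truth, config = cfg),
            class = "sim_result")
}

# one recombinant gamete per parent index; rfrac[j] is the recombination
# fraction between locus j-1 and j (0.5 at linkage-group starts)
.make_gametes <- function(A1, A2, parents, rfrac) {
  n <- length(parents)
  L <- ncol(A1)
  P1 <- A1[parents, , drop = FALSE]
  P2 <- A2[parents, , drop = FALSE]
  gam <- P1
  cur <- stats::runif(n) < 0.5  # phase at the first locus
  for (j in seq_len(L)) {
    if (j > 1) {
      flip <- stats::runif(n) < rfrac[j]
      if (rfrac[j] >= 0.5) {
        cur <- flip  # free recombination: fresh phase
      } else {
        cur <- xor(cur, flip)
      }
    }
    if (any(cur)) gam[cur, j] <- P2[cur, j]
  }
  gam
}

#' Flax-collection-like simulation preset
#'
#' A documented default parameterisation emulating the kind of material the
#' package targets: a predominantly selfing crop collection with two major
#' group-clusters of demes, 15 linkage groups, roughly 5 alleles per locus,
#' near-zero observed heterozygosity (selfing 0.98) and mild structure
#' (group-level FST around 0.1). These targets are calibration goals
#' recorded in the simulation truth, not guarantees.
#'
#' @param seed RNG seed.
#' @param n_loci Number of loci.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
flaxlike_preset <- function(seed = 1L, n_loci = 50L, ...) {
  args <- list(
    seed = seed, n_demes = 6L, deme_size = 60L, n_groups = 2L,
    migration_within = 0.05, migration_between = 0.012,
    selfing_rate = 0.98, n_generations = 150L, n_loci = n_loci,
    n_linkage_groups = 15L, mutation_model = "SMM", mutation_rate = 1e-3,
    founder_k = 4L, founder_concentration = 1,
    sample_sizes = 25L, missing_rate = 0.01, null_allele_rate = 2e-4
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' @rdname flaxlike_preset
#' @param genotypes_only Unused convenience switch kept for symmetry.
#' @export
sim_flaxlike <- function(seed = 1L, n_loci = 50L, ..., genotypes_only = FALSE) {
  res <- simulate_ssr(flaxlike_preset(seed = seed, n_loci = n_loci, ...))
  if (genotypes_only) res$genotypes else res
}

#' Plant a sweep signature into a genotype matrix
#'
#' Engineers the footprint of a completed divergent sweep at chosen loci:
#' within the target individuals, each allele copy is replaced by the
#' locus's designated allele with probability `target_freq` (the rest of
#' the matrix is untouched, so the background stays exactly as generated).
#' The favoured allele is the segregating allele of the target group with
#' the lowest frequency outside it, maximising the between-group contrast,
#' as after strong selection on a locally adaptive variant.
#'
#' @param gm A [geno_matrix()].
#' @param loci Character vector of loci to engineer.
#' @param individuals Character vector of target-group individual ids.
#' @param target_freq Post-sweep frequency of the favoured allele in the
#'   target group (near-fixation by default).
#' @return The modified `geno_matrix`, with the chosen alleles recorded in
#'   attribute `"sweep_alleles"`.
#' @export
plant_sweeps <- function(gm, loci, individuals, target_freq = 0.95) {
  idx <- match(individuals, rownames(gm$a1))
  if (anyNA(idx)) stop("unknown individuals", call. = FALSE)
  chosen <- integer(0)
  for (l in loci) {
    j <- match(l, colnames(gm$a1))
    if (is.na(j)) stop("unknown locus ", l, call. = FALSE)
    inside <- c(gm$a1[idx, j], gm$a2[idx, j])
    outside <- c(gm$a1[-idx, j], gm$a2[-idx, j])
    cand <- unique(stats::na.omit(inside))
    if (!length(cand)) next
    freq_out <- vapply(cand, function(a) mean(outside == a, na.rm = TRUE),
                       numeric(1))
    fav <- cand[which.min(freq_out)]
    for (slot in c("a1", "a2")) {
      col <- gm[[slot]][idx, j]
      hit <- !is.na(col) & stats::runif(length(col)) < target_freq
      col[hit] <- fav
      gm[[slot]][idx, j] <- col
    }
    # keep cells canonically sorted
    swap <- !is.na(gm$a1[, j]) & gm$a1[, j] > gm$a2[, j]
    if (any(swap)) {
      tmp <- gm$a1[swap, j]
      gm$a1[swap, j] <- gm$a2[swap, j]
      gm$a2[swap, j] <- tmp
    }
    chosen[l] <- fav
  }
  attr(gm, "sweep_alleles") <- chosen
  gm
}
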