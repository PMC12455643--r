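#' Synthetic gene annotation for a simulated genome
#'
#' Builds an evenly spaced single-replicon gene set used by the ALE
#' simulator. Gene sizes and spacing echo a small cyanobacterial chromosome:
#' most of the sequence is intergenic, so false-positive calls drawn
#' uniformly over the genome rarely fall inside genes.
#'
#' @param n_genes Number of genes (default 30).
#' @param gene_length Gene length in bp (default 900).
#' @param genome_length Replicon length in bp (default 3.5e6).
#' @param seq_id Sequence name (default `"chr1"`).
#' @return A gene annotation tibble (`gene_id`, `seq_id`, `start`, `end`,
#'   `strand`).
#' @export
synthetic_annotation <- function(n_genes = 30, gene_length = 900,
                                 genome_length = 3.5e6, seq_id = "chr1") {
  stopifnot(n_genes >= 1, gene_length >= 1,
            genome_length >= n_genes * gene_length)
  spacing <- floor(genome_length / n_genes)
  start <- (seq_len(n_genes) - 1L) * spacing + 1L
  tibble::tibble(
    gene_id = sprintf("gene_%02d", seq_len(n_genes)),
    seq_id = seq_id,
    start = start,
    end = start + gene_length - 1L,
    strand = rep(c("+", "-"), length.out = n_genes)
  )
}

#' Salt schedule for a serial-transfer experiment
#'
#' Either a constant concentration or a stepwise ramp in which the simulator
#' raises salt by `step_mM` (to at most `max_mM`) whenever the population's
#' growth rate has stabilized at or above the rate reached at the end of the
#' previous level — the same decision rule as [salt_step_controller()].
#'
#' @param mode `"stepwise"` (default) or `"constant"`.
#' @param start_mM Starting concentration, mM (default 200).
#' @param step_mM Increment, mM (default 50).
#' @param max_mM Ceiling, mM (default 400).
#' @return A `salt_schedule` list.
#' @export
salt_schedule <- function(mode = c("stepwise", "constant"), start_mM = 200,
                          step_mM = 50, max_mM = 400) {
  mode <- match.arg(mode)
  stopifnot(start_mM >= 0, step_mM > 0, max_mM >= start_mM)
  structure(list(mode = mode, start_mM = start_mM, step_mM = step_mM,
                 max_mM = max_mM), class = "salt_schedule")
}

#' Configuration of the serial-transfer ALE simulator
#'
#' Collects and validates all simulator parameters. The defaults describe
#' the study conditions the package is built around: a polyploid
#' cyanobacterium (10 chromosome copies per cell) evolved by growth-dilution
#' cycles from OD730 0.05 to ~2.0 (log2(40) ~ 5.32 generations per
#' transfer) under stepwise salt stress from 200 to 400 mM in 50 mM steps,
#' with two planted driver genes whose benefit scales linearly with salt
#' above a reference concentration, a background of standing neutral
#' variation partially segregated across chromosome copies, and
#' polymorphism-mode resequencing at depth 100 with abundant low-frequency
#' false-positive calls.
#'
#' @param seed Integer seed; all stochastic draws come from one generator
#'   seeded here.
#' @param ploidy Chromosome copies per cell, `P` (default 10).
#' @param bottleneck_size Cells sampled at each dilution, `N_b`
#'   (default 10000, minimum 100).
#' @param od_initial,od_final ODs defining a transfer (defaults 0.05, 2.0).
#' @param n_transfers Number of growth-dilution cycles (default 20).
#' @param mutation_rate Expected new mutations per transfer, Poisson
#'   (default 3).
#' @param driver_genes Named numeric vector: maximum selection coefficient
#'   (per 100 mM salt above `salt_ref_mM`) for each driver gene id.
#' @param salt_ref_mM Salt concentration at and below which drivers confer
#'   no benefit (default 100).
#' @param deleterious_fraction Fraction of new mutations that carry a
#'   fitness cost (default 0.1).
#' @param deleterious_s Cost per deleterious mutation (default 0.05).
#' @param salt_schedule A [salt_schedule()].
#' @param sequencing_depth Reads per site for the sequencing emulator
#'   (default 100).
#' @param fp_rate Expected spurious calls per isolate (default 20).
#' @param fp_freq_shape `c(shape1, shape2)` of the Beta distribution of
#'   false-positive frequencies (default `c(1, 9)`, mean 0.1).
#' @param standing_lineages Number of pre-existing parental lineages
#'   (default 10).
#' @param standing_muts_per_lineage Private neutral mutations per standing
#'   lineage (default 18).
#' @param standing_copy_fraction If given, all standing mutations start at
#'   this copy fraction; otherwise fractions are drawn uniformly from the
#'   1/P lattice.
#' @param driver_init_abundance Founding abundance of the adapted lineage
#'   that carries one driver mutation per driver gene (default 0.02).
#' @param driver_init_copy_fraction Initial within-cell copy fraction of the
#'   planted driver mutations (default 1.0, i.e. fully segregated).
#' @param mu_ref Reference growth rate, h^-1, of an unadapted population at
#'   the starting salt (default 0.052).
#' @param salt_cost_per_100mM Relative growth-rate penalty per 100 mM salt
#'   above the starting concentration (default 0.15).
#' @param infinite_bottleneck If `TRUE`, the multinomial dilution step is
#'   replaced by its deterministic infinite-population limit.
#' @param annotation Gene annotation tibble; defaults to
#'   [synthetic_annotation()] with genes covering the configured driver ids.
#' @param genome_length Replicon length for drawing mutation positions.
#' @return An `ale_config` list.
#' @export
ale_config <- function(seed = 1L,
                       ploidy = 10L,
                       bottleneck_size = 10000L,
                       od_initial = 0.05,
                       od_final = 2.0,
                       n_transfers = 20L,
                       mutation_rate = 3,
                       driver_genes = c(gene_05 = 0.25, gene_17 = 0.25),
                       salt_ref_mM = 100,
                       deleterious_fraction = 0.1,
                       deleterious_s = 0.05,
                       salt_schedule = alevar::salt_schedule(),
                       sequencing_depth = 100L,
                       fp_rate = 20,
                       fp_freq_shape = c(1, 9),
                       standing_lineages = 10L,
                       standing_muts_per_lineage = 18L,
                       standing_copy_fraction = NULL,
                       driver_init_abundance = 0.02,
                       driver_init_copy_fraction = 1.0,
                       mu_ref = 0.052,
                       salt_cost_per_100mM = 0.15,
                       infinite_bottleneck = FALSE,
                       annotation = NULL,
                       genome_length = 3.5e6) {
  cfg <- list(
    seed = as.integer(seed), ploidy = as.integer(ploidy),
    bottleneck_size = as.integer(bottleneck_size),
    od_initial = od_initial, od_final = od_final,
    n_transfers = as.integer(n_transfers), mutation_rate = mutation_rate,
    driver_genes = driver_genes, salt_ref_mM = salt_ref_mM,
    deleterious_fraction = deleterious_fraction, deleterious_s = deleterious_s,
    salt_schedule = salt_schedule,
    sequencing_depth = as.integer(sequencing_depth),
    fp_rate = fp_rate, fp_freq_shape = fp_freq_shape,
    standing_lineages = as.integer(standing_lineages),
    standing_muts_per_lineage = as.integer(standing_muts_per_lineage),
    standing_copy_fraction = standing_copy_fraction,
    driver_init_abundance = driver_init_abundance,
    driver_init_copy_fraction = driver_init_copy_fraction,
    mu_ref = mu_ref, salt_cost_per_100mM = salt_cost_per_100mM,
    infinite_bottleneck = isTRUE(infinite_bottleneck),
    annotation = annotation, genome_length = genome_length
  )
  if (is.null(cfg$annotation)) cfg$annotation <- synthetic_annotation()
  validate_config(cfg)
  structure(cfg, class = "ale_config")
}

validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid config field `", field, "`: ", msg, call. = FALSE)
  }
  if (is.na(cfg$ploidy) || cfg$ploidy < 1) fail("ploidy", "must be >= 1")
  if (!(cfg$od_initial > 0 && cfg$od_initial < cfg$od_final)) {
    fail("od_initial", "need 0 < od_initial < od_final")
  }
  if (is.na(cfg$bottleneck_size) || cfg$bottleneck_size < 100) {
    fail("bottleneck_size", "must be >= 100")
  }
  if (cfg$mutation_rate < 0) fail("mutation_rate", "must be >= 0")
  if (cfg$sequencing_depth < 1) fail("sequencing_depth", "must be >= 1")
  if (length(cfg$driver_genes) > 0) {
    if (is.null(names(cfg$driver_genes)) || any(!nzchar(names(cfg$driver_genes)))) {
      fail("driver_genes", "must be a named numeric vector (gene id -> s_max)")
    }
    if (any(!is.finite(cfg$driver_genes))) fail("driver_genes", "s_max must be finite")
    missing_genes <- setdiff(names(cfg$driver_genes), cfg$annotation$gene_id)
    if (length(missing_genes) > 0) {
      fail("driver_genes", paste("not in annotation:",
                                 paste(missing_genes, collapse = ", ")))
    }
  }
  if (!is.finite(cfg$deleterious_s) || cfg$deleterious_s < 0) {
    fail("deleterious_s", "must be finite and >= 0")
  }
  if (cfg$n_transfers < 1) fail("n_transfers", "must be >= 1")
  if (cfg$fp_rate < 0) fail("fp_rate", "must be >= 0")
  if (length(cfg$fp_freq_shape) != 2 || any(cfg$fp_freq_shape <= 0)) {
    fail("fp_freq_shape", "must be two positive Beta shape parameters")
  }
  invisible(cfg)
}

# -- internal helpers ---------------------------------------------------------

BASES <- c("A", "C", "G", "T")

random_mutation_detail <- function(type) {
  switch(type,
    SNP = {
      ref <- sample(BASES, 1)
      alt <- sample(setdiff(BASES, ref), 1)
      paste0(ref, ">", alt)
    },
    INS = paste(sample(BASES, sample.int(12, 1), replace = TRUE), collapse = ""),
    DEL = as.character(sample.int(30, 1))
  )
}

draw_position <- function(lo, hi, used) {
  repeat {
    pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    if (!(pos %in% used)) return(pos)
  }
}

#' Simulate a serial-transfer ALE experiment in a polyploid organism
#'
#' Lineage-based Wright-Fisher simulation of growth-dilution cycles. Each
#' transfer consists of (i) deterministic selection: lineage abundances are
#' reweighted by `w(salt)^g` with `g = log2(od_final/od_initial)` doublings;
#' (ii) mutation: a Poisson number of new mutations founds daughter lineages
#' (one cell each) at within-cell copy fraction `1/P`; (iii) neutral
#' intracellular segregation: every partially segregated copy fraction is
#' resampled once per generation as `Binomial(P, c)/P` — the mechanism that
#' produces clonal-isolate read-support frequencies strictly between 0
#' and 1; and (iv) a multinomial bottleneck of `bottleneck_size` cells.
#' Lineage fitness is `prod(1 + s_m(salt) * c_m)` over carried mutations,
#' with driver coefficients scaling linearly with salt above the reference
#' concentration. Under a stepwise schedule the salt concentration follows
#' the [salt_step_controller()] rule applied to the population growth rate.
#'
#' @param config An [ale_config()].
#' @return An `ale_sim` object: ground-truth `mutations` table, population
#'   `trajectory` (transfer, salt_mM, mutation_id, frequency), `growth`
#'   (transfer, salt_mM, mu, mean_fitness), per-transfer lineage
#'   `snapshots`, `generations` per transfer, and a `status`
#'   (`"ok"`/`"extinct"`). Identical config and seed reproduce the result
#'   exactly.
#' @export
simulate_ale <- function(config) {
  stopifnot(inherits(config, "ale_config"))
  validate_config(config)
  set.seed(config$seed)
  P <- config$ploidy
  g <- generations_per_transfer(config$od_initial, config$od_final)
  ann <- config$annotation
  seq_id <- ann$seq_id[1]
  sched <- config$salt_schedule

  # growing mutation registry
  reg <- new.env(parent = emptyenv())
  reg$id <- character(0); reg$gene <- character(0); reg$pos <- integer(0)
  reg$type <- character(0); reg$detail <- character(0)
  reg$role <- character(0); reg$s <- numeric(0)
  used_positions <- integer(0)

  add_mutation <- function(gene_id, role, s) {
    type <- sample(c("SNP", "INS", "DEL"), 1, prob = c(0.7, 0.15, 0.15))
    detail <- random_mutation_detail(type)
    if (gene_id == "intergenic") {
      pos <- draw_position(1L, as.integer(config$genome_length), used_positions)
    } else {
      row <- ann[ann$gene_id == gene_id, ]
      pos <- draw_position(row$start, row$end, used_positions)
    }
    used_positions <<- c(used_positions, pos)
    id <- mutation_key(seq_id, pos, type, detail)
    reg$id <- c(reg$id, id); reg$gene <- c(reg$gene, gene_id)
    reg$pos <- c(reg$pos, pos); reg$type <- c(reg$type, type)
    reg$detail <- c(reg$detail, detail); reg$role <- c(reg$role, role)
    reg$s <- c(reg$s, s)
    id
  }

  # initial population: standing neutral lineages + one adapted founder
  non_driver <- setdiff(ann$gene_id, names(config$driver_genes))
  n_stand <- config$standing_lineages
  if (n_stand == 0 && length(config$driver_genes) == 0) {
    stop("population needs at least one standing lineage or driver founder",
         call. = FALSE)
  }
  x <- if (n_stand > 0) stats::rexp(n_stand) else numeric(0)
  if (n_stand > 0) x <- x / sum(x)
  C <- matrix(0, nrow = 0, ncol = n_stand)  # mutations x lineages copy fractions
  mut_ids <- character(0)
  for (l in seq_len(n_stand)) {
    for (k in seq_len(config$standing_muts_per_lineage)) {
      gene <- sample(non_driver, 1)
      id <- add_mutation(gene, "neutral", 0)
      cfrac <- if (is.null(config$standing_copy_fraction)) {
        sample.int(P, 1) / P
      } else config$standing_copy_fraction
      C <- rbind(C, matrix(0, 1, ncol(C)))
      C[nrow(C), l] <- cfrac
      mut_ids <- c(mut_ids, id)
    }
  }
  if (length(config$driver_genes) > 0) {
    x <- c(x * (1 - config$driver_init_abundance), config$driver_init_abundance)
    C <- cbind(C, matrix(0, nrow(C), 1))
    for (gname in names(config$driver_genes)) {
      id <- add_mutation(gname, "driver", unname(config$driver_genes[gname]))
      C <- rbind(C, matrix(0, 1, ncol(C)))
      C[nrow(C), ncol(C)] <- config$driver_init_copy_fraction
      mut_ids <- c(mut_ids, id)
    }
  }
  rownames(C) <- mut_ids
  x <- x / sum(x)
  lineage_ids <- seq_len(length(x))
  next_lineage <- length(x) + 1L

  s_eff <- function(salt) {
    s <- reg$s[match(rownames(C), reg$id)]
    role <- reg$role[match(rownames(C), reg$id)]
    ifelse(role == "driver", s * max(0, salt - config$salt_ref_mM) / 100, s)
  }

  snapshots <- vector("list", config$n_transfers + 1L)
  snapshots[[1]] <- list(lineage_ids = lineage_ids, abundance = x, copies = C)
  traj <- vector("list", config$n_transfers)
  growth_rows <- vector("list", config$n_transfers)
  salt_now <- sched$start_mM
  mu_history <- tibble::tibble(salt_mM = numeric(0), mu = numeric(0))
  status <- "ok"
  realized_salt <- numeric(0)

  for (t in seq_len(config$n_transfers)) {
    # salt level for this transfer (stepwise: controller on stabilized rates)
    if (sched$mode == "stepwise" && nrow(mu_history) >= 2) {
      cur <- mu_history$mu[mu_history$salt_mM == salt_now]
      if (is_stabilized(cur)) {
        salt_now <- salt_step_controller(mu_history, sched$step_mM, sched$max_mM)
      }
    }
    realized_salt <- c(realized_salt, salt_now)

    # selection over g doublings
    se <- s_eff(salt_now)
    w <- apply(1 + se * C, 2, prod)
    if (all(w <= 0)) {
      status <- "extinct"
      break
    }
    w <- pmax(w, 0)
    x <- x * w^g
    if (sum(x) <= 0 || !all(is.finite(x))) {
      status <- "extinct"
      break
    }
    x <- x / sum(x)

    # population growth rate under this salt: reference rate, a linear
    # osmotic penalty, and the population mean per-generation fitness
    mean_w <- sum(x * w)
    mu_pop <- max(config$mu_ref *
                    (1 - config$salt_cost_per_100mM *
                       (salt_now - sched$start_mM) / 100) * mean_w, 1e-4)
    mu_history <- dplyr::bind_rows(mu_history,
                                   tibble::tibble(salt_mM = salt_now, mu = mu_pop))

    # new mutations found daughter lineages (one cell each)
    n_new <- stats::rpois(1, config$mutation_rate)
    for (i in seq_len(n_new)) {
      parent <- sample.int(length(x), 1, prob = x)
      role <- if (stats::runif(1) < config$deleterious_fraction) "deleterious" else "neutral"
      s <- if (role == "deleterious") -config$deleterious_s else 0
      gene <- sample(non_driver, 1)
      id <- add_mutation(gene, role, s)
      cell <- min(1 / config$bottleneck_size, x[parent])
      x[parent] <- x[parent] - cell
      x <- c(x, cell)
      C <- cbind(C, C[, parent, drop = FALSE])
      C <- rbind(C, matrix(0, 1, ncol(C)))
      C[nrow(C), ncol(C)] <- 1 / P
      rownames(C)[nrow(C)] <- id
      lineage_ids <- c(lineage_ids, next_lineage)
      next_lineage <- next_lineage + 1L
    }

    # neutral intracellular segregation, once per generation
    n_rounds <- floor(g) + (stats::runif(1) < g %% 1)
    interior <- which(C > 0 & C < 1)
    if (length(interior) > 0) {
      for (r in seq_len(n_rounds)) {
        C[interior] <- stats::rbinom(length(interior), P, C[interior]) / P
      }
    }

    # dilution bottleneck
    if (!config$infinite_bottleneck) {
      counts <- as.vector(stats::rmultinom(1, config$bottleneck_size, x))
      x <- counts / config$bottleneck_size
    }
    alive <- x > 0
    x <- x[alive]
    lineage_ids <- lineage_ids[alive]
    C <- C[, alive, drop = FALSE]
    if (length(x) == 0) {
      status <- "extinct"
      break
    }
    x <- x / sum(x)
    carried <- rowSums(C) > 0
    C <- C[carried, , drop = FALSE]

    snapshots[[t + 1L]] <- list(lineage_ids = lineage_ids, abundance = x,
                                copies = C)
    freq <- as.vector(C %*% x)
    traj[[t]] <- tibble::tibble(transfer = t, salt_mM = salt_now,
                                mutation_id = rownames(C), frequency = freq)
    growth_rows[[t]] <- tibble::tibble(transfer = t, salt_mM = salt_now,
                                       mu = mu_pop, mean_fitness = mean_w)
  }

  mutations <- tibble::tibble(
    mutation_id = reg$id, gene_id = reg$gene, seq_id = seq_id,
    position = reg$pos, type = reg$type, detail = reg$detail,
    role = reg$role, s = reg$s
  )
  structure(list(
    config = config,
    annotation = ann,
    mutations = mutations,
    trajectory = dplyr::bind_rows(traj),
    growth = dplyr::bind_rows(growth_rows),
    snapshots = snapshots,
    generations = g,
    realized_salt = realized_salt,
    genome = list(seq_id = seq_id, length = config$genome_length,
                  used_positions = used_positions),
    status = status
  ), class = "ale_sim")
}

#' @export
print.ale_sim <- function(x, ...) {
  cat("<ale_sim> ", length(x$realized_salt), " transfer(s), ",
      nrow(x$mutations), " mutation(s), status: ", x$status, "\n", sep = "")
  cat("salt (mM):", paste(unique(x$realized_salt), collapse = " -> "), "\n")
  invisible(x)
}

#' @describeIn simulate_ale Population mutation-frequency trajectories as a
#'   long tibble (joined with ground-truth roles).
#' @param x An `ale_sim` object.
#' @param ... Unused.
#' @export
tidy.ale_sim <- function(x, ...) {
  dplyr::left_join(x$trajectory,
                   x$mutations[, c("mutation_id", "gene_id", "role")],
                   by = "mutation_id")
}

#' @describeIn simulate_ale One-row summary of the run.
#' @export
glance.ale_sim <- function(x, ...) {
  tibble::tibble(
    n_transfers = length(x$realized_salt),
    n_mutations = nrow(x$mutations),
    n_driver = sum(x$mutations$role == "driver"),
    final_salt_mM = if (length(x$realized_salt)) {
      x$realized_salt[length(x$realized_salt)]
    } else NA_real_,
    generations_per_transfer = x$generations,
    status = x$status
  )
}

#' Pick clonal isolates from a simulated population
#'
#' Emulates picking random single colonies: each isolate is one lineage
#' drawn with probability proportional to its abundance at the requested
#' transfer. An isolate's mutation frequencies are its lineage's within-cell
#' copy fractions, so partially segregated mutations yield clonal
#' frequencies strictly between 0 and 1.
#'
#' @param sim An `ale_sim` object.
#' @param n_parental,n_evolved Isolates per group (defaults 3 and 3).
#' @param parental_transfer Transfer index for the parental panel (0 = the
#'   founding population; default 0).
#' @param evolved_transfer Transfer index for the evolved panel (default:
#'   the last transfer).
#' @param seed Integer seed for the draws.
#' @return An `ale_panel`: `isolates` tibble (`isolate_id`, `group`,
#'   `lineage_id`, `transfer`) and `copies` tibble (`isolate_id`,
#'   `mutation_id`, `copy_fraction` for carried mutations).
#' @export
sample_isolates <- function(sim, n_parental = 3, n_evolved = 3,
                            parental_transfer = 0,
                            evolved_transfer = NULL, seed = 1L) {
  stopifnot(inherits(sim, "ale_sim"))
  if (is.null(evolved_transfer)) evolved_transfer <- length(sim$realized_salt)
  set.seed(as.integer(seed))
  pick <- function(transfer, n, prefix, group) {
    if (transfer < 0 || transfer + 1L > length(sim$snapshots) ||
        is.null(sim$snapshots[[transfer + 1L]])) {
      stop("transfer ", transfer, " not present in simulation", call. = FALSE)
    }
    snap <- sim$snapshots[[transfer + 1L]]
    if (length(snap$abundance) == 0 || sum(snap$abundance) <= 0) {
      stop("population empty at transfer ", transfer, call. = FALSE)
    }
    idx <- sample.int(length(snap$abundance), n, replace = TRUE,
                      prob = snap$abundance)
    iso <- tibble::tibble(
      isolate_id = sprintf("%s_%d", prefix, seq_len(n)),
      group = group,
      lineage_id = snap$lineage_ids[idx],
      transfer = transfer
    )
    copies <- purrr::map_dfr(seq_len(n), function(i) {
      cf <- snap$copies[, idx[i]]
      carried <- cf > 0
      tibble::tibble(isolate_id = iso$isolate_id[i],
                     mutation_id = rownames(snap$copies)[carried],
                     copy_fraction = unname(cf[carried]))
    })
    list(isolates = iso, copies = copies)
  }
  par <- pick(parental_transfer, n_parental, "OMP", "parental")
  evo <- pick(evolved_transfer, n_evolved, "EMP", "evolved")
  structure(list(
    isolates = dplyr::bind_rows(par$isolates, evo$isolates),
    copies = dplyr::bind_rows(par$copies, evo$copies),
    mutations = sim$mutations,
    genome = sim$genome
  ), class = "ale_panel")
}

#' @export
print.ale_panel <- function(x, ...) {
  cat("<ale_panel> ", nrow(x$isolates), " isolates (",
      sum(x$isolates$group == "parental"), " parental, ",
      sum(x$isolates$group == "evolved"), " evolved), ",
      nrow(x$copies), " carried mutation states\n", sep = "")
  invisible(x)
}

#' Emulate polymorphism-mode resequencing of an isolate panel
#'
#' Converts clonal copy fractions into read-support frequencies: for each
#' carried mutation the reported frequency is `k/depth` with
#' `k ~ Binomial(depth, copy_fraction)`; mutations with no supporting read
#' are absent from the output (frequency 0 by downstream convention). Each
#' isolate additionally receives a Poisson number of spurious calls at novel,
#' never-reused genome positions with frequencies from a low-frequency Beta
#' distribution — mimicking the inflation of false positives that
#' polymorphism-mode calling brings.
#'
#' @param panel An `ale_panel` from [sample_isolates()].
#' @param depth Reads per site (default 100).
#' @param fp_rate Expected false-positive calls per isolate (default 20).
#' @param fp_freq_shape Beta shape parameters of the false-positive
#'   frequency distribution (default `c(1, 9)`).
#' @param seed Integer seed.
#' @return A tibble of mutation records (see [read_frequency_table()] for
#'   columns) with attributes `fp_ids` (identifiers of the spurious calls)
#'   and `isolates` (the panel's isolate table).
#' @export
emulate_sequencing <- function(panel, depth = 100, fp_rate = 20,
                               fp_freq_shape = c(1, 9), seed = 1L) {
  stopifnot(inherits(panel, "ale_panel"))
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (fp_rate < 0) stop("fp_rate must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  depth <- as.integer(depth)

  obs <- panel$copies
  k <- stats::rbinom(nrow(obs), depth, obs$copy_fraction)
  keep <- k > 0
  meta <- panel$mutations[match(obs$mutation_id[keep], panel$mutations$mutation_id), ]
  true_records <- tibble::tibble(
    mutation_id = obs$mutation_id[keep],
    type = meta$type, seq_id = meta$seq_id, position = meta$position,
    detail = meta$detail,
    isolate_id = obs$isolate_id[keep],
    frequency = k[keep] / depth
  )

  used <- panel$genome$used_positions
  fp_rows <- list()
  for (iso in panel$isolates$isolate_id) {
    n_fp <- stats::rpois(1, fp_rate)
    for (i in seq_len(n_fp)) {
      pos <- draw_position(1L, as.integer(panel$genome$length), used)
      used <- c(used, pos)
      detail <- random_mutation_detail("SNP")
      p <- stats::rbeta(1, fp_freq_shape[1], fp_freq_shape[2])
      kk <- max(stats::rbinom(1, depth, p), 1L)
      fp_rows[[length(fp_rows) + 1L]] <- tibble::tibble(
        mutation_id = mutation_key(panel$genome$seq_id, pos, "SNP", detail),
        type = "SNP", seq_id = panel$genome$seq_id, position = pos,
        detail = detail, isolate_id = iso, frequency = kk / depth
      )
    }
  }
  fp_records <- dplyr::bind_rows(fp_rows)
  out <- dplyr::bind_rows(true_records, fp_records)
  out <- validate_records(out, where = "emulated records")
  attr(out, "fp_ids") <- if (nrow(fp_records)) fp_records$mutation_id else character(0)
  attr(out, "isolates") <- panel$isolates[, c("isolate_id", "group")]
  out
}
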