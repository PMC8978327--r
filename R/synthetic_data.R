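# Synthetic tri-omics generator. Produces circRNA / miRNA / mRNA count and
# normalized matrices over the four B-cell stages with planted, recorded
# structure: stage-specific transcripts, adjacent-stage fold changes,
# temporal sign-word patterns, and ceRNA sponge triplets whose sequences
# carry canonical seed sites. The planted record is the oracle every
# downstream pipeline stage is tested against.

.default_pattern_labels <- c("up-up-up", "down-down-down", "down-up-down",
                             "up-down-up", "down-up-flat", "up-down-down")

#' Simulation configuration
#'
#' Parameterizes [generate_dataset()]. Defaults emulate the data regime of
#' a four-stage bone-marrow B-cell sorting experiment: about a thousand
#' circRNAs, ~1600 miRNAs and ~9800 mRNAs, with ~60 percent of circRNAs but
#' under ~10 percent of miRNAs/mRNAs stage-specific, pooled (replicate-free)
#' libraries, and planted four-fold adjacent-stage effects.
#'
#' @param n_circ,n_mirna,n_mrna Transcripts per omics layer.
#' @param frac_stage_specific Fraction of each layer expressed in exactly
#'   one stage; scalar or length 3 (circ, mirna, mrna order).
#' @param n_planted_patterns Planted circRNAs per temporal pattern label.
#' @param pattern_labels Pattern labels to plant (subset of
#'   [pattern_labels_all()]).
#' @param pattern_step Per-transition fold step used when planting patterns
#'   (> 1; up multiplies by it, down divides).
#' @param n_planted_de Planted DE transcripts per layer per comparison per
#'   direction (beyond triplet members).
#' @param n_planted_triplets Planted ceRNA triplets per exclusive
#'   comparison group.
#' @param de_fold_change Planted fold change (> 1) for DE effects.
#' @param sequencing_depth Library size per stage (scalar or length 4);
#'   the denominator of the per-million normalizations.
#' @param noise_model `"poisson"` or `"negative_binomial"`.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion);
#'   ignored for Poisson.
#' @param baseline_mean Mean count of an expressed transcript at baseline.
#' @param replicates_per_stage Pooled replicate draws per stage (counts are
#'   summed, library sizes scaled accordingly; default 1, the pooled
#'   single-library design).
#' @param hard_planting When TRUE, counts are the rounded expected counts
#'   and normalized values are computed from the exact means (sampling is
#'   bypassed), so planted structure is recovered deterministically.
#' @param with_sequences Generate miRNA/target sequences with planted seed
#'   sites for the planted triplets.
#' @param sequence_scope `"planted"` (sequences only for planted triplet
#'   members; background is guaranteed free of spurious sites) or `"all"`.
#' @param target_length,mirna_length Sequence lengths (nt).
#' @param rng_seed Integer seed; identical config + seed reproduces the
#'   dataset bit-identically.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(n_circ = 1000, n_mirna = 1600, n_mrna = 9800,
                              frac_stage_specific = c(circ = 0.60,
                                                      mirna = 0.08,
                                                      mrna = 0.08),
                              n_planted_patterns = 5,
                              pattern_labels = .default_pattern_labels,
                              pattern_step = 2,
                              n_planted_de = 20,
                              n_planted_triplets = 5,
                              de_fold_change = 4,
                              sequencing_depth = 1e6,
                              noise_model = c("poisson", "negative_binomial"),
                              dispersion = 0.1,
                              baseline_mean = 100,
                              replicates_per_stage = 1,
                              hard_planting = FALSE,
                              with_sequences = TRUE,
                              sequence_scope = c("planted", "all"),
                              target_length = 300,
                              mirna_length = 22,
                              rng_seed = 1) {
  noise_model <- match.arg(noise_model)
  sequence_scope <- match.arg(sequence_scope)
  chk_count <- function(x, nm) {
    .stop_if(length(x) != 1L || is.na(x) || x < 0 || x != floor(x),
             "`", nm, "` must be a single nonnegative integer")
  }
  chk_count(n_circ, "n_circ"); chk_count(n_mirna, "n_mirna")
  chk_count(n_mrna, "n_mrna")
  chk_count(n_planted_patterns, "n_planted_patterns")
  chk_count(n_planted_de, "n_planted_de")
  chk_count(n_planted_triplets, "n_planted_triplets")
  frac_stage_specific <- unlist(frac_stage_specific)
  sequencing_depth <- unlist(sequencing_depth)
  if (length(frac_stage_specific) == 1L) {
    frac_stage_specific <- rep(frac_stage_specific, 3L)
  }
  .stop_if(length(frac_stage_specific) != 3L,
           "`frac_stage_specific` must be a scalar or length 3")
  names(frac_stage_specific) <- c("circ", "mirna", "mrna")
  .stop_if(any(frac_stage_specific < 0 | frac_stage_specific > 1),
           "`frac_stage_specific` must lie in [0, 1]")
  .stop_if(n_planted_triplets > min(n_circ, n_mirna, n_mrna),
           "n_planted_triplets (", n_planted_triplets,
           ") exceeds min(n_circ, n_mirna, n_mrna) = ",
           min(n_circ, n_mirna, n_mrna))
  bad_lab <- setdiff(pattern_labels, pattern_labels_all())
  .stop_if(length(bad_lab) > 0,
           "unknown pattern label(s): ", paste(bad_lab, collapse = ", "))
  .stop_if(pattern_step <= 1, "`pattern_step` must be > 1")
  .stop_if(de_fold_change <= 1, "`de_fold_change` must be > 1")
  if (length(sequencing_depth) == 1L) sequencing_depth <- rep(sequencing_depth, 4L)
  .stop_if(length(sequencing_depth) != 4L || any(sequencing_depth <= 0),
           "`sequencing_depth` must be positive, scalar or length 4")
  .stop_if(dispersion <= 0, "`dispersion` must be positive")
  .stop_if(baseline_mean <= 0, "`baseline_mean` must be positive")
  .stop_if(replicates_per_stage < 1 ||
             replicates_per_stage != floor(replicates_per_stage),
           "`replicates_per_stage` must be a positive integer")
  .stop_if(mirna_length < 8, "`mirna_length` must be at least 8 nt")
  .stop_if(target_length < 8, "`target_length` must be at least 8 nt")
  .stop_if(length(rng_seed) != 1L || is.na(rng_seed) ||
             rng_seed != floor(rng_seed), "`rng_seed` must be an integer")
  cfg <- list(
    n_circ = as.integer(n_circ), n_mirna = as.integer(n_mirna),
    n_mrna = as.integer(n_mrna),
    frac_stage_specific = frac_stage_specific,
    n_planted_patterns = as.integer(n_planted_patterns),
    pattern_labels = pattern_labels,
    pattern_step = pattern_step,
    n_planted_de = as.integer(n_planted_de),
    n_planted_triplets = as.integer(n_planted_triplets),
    de_fold_change = de_fold_change,
    sequencing_depth = stats::setNames(sequencing_depth, b_cell_stages()),
    noise_model = noise_model,
    dispersion = dispersion,
    baseline_mean = baseline_mean,
    replicates_per_stage = as.integer(replicates_per_stage),
    hard_planting = isTRUE(hard_planting),
    with_sequences = isTRUE(with_sequences),
    sequence_scope = sequence_scope,
    target_length = as.integer(target_length),
    mirna_length = as.integer(mirna_length),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# random expressed-stage structure for one layer
.layer_structure <- function(n, prefix, frac) {
  stages <- b_cell_stages()
  ids <- sprintf("%s_%05d", prefix, seq_len(n))
  expressed <- matrix(FALSE, n, 4L, dimnames = list(ids, stages))
  specific <- stats::setNames(rep(NA_character_, n), ids)
  if (n > 0L) {
    is_spec <- stats::runif(n) < frac
    for (i in seq_len(n)) {
      if (is_spec[i]) {
        s <- sample.int(4L, 1L)
        expressed[i, s] <- TRUE
        specific[i] <- stages[s]
      } else {
        k <- sample(2:4, 1L)
        expressed[i, sample.int(4L, k)] <- TRUE
      }
    }
  }
  list(ids = ids, expressed = expressed, specific = specific)
}

# stage multiplier vector for a fold change planted in comparison j
.step_multiplier <- function(j, direction, fc) {
  v <- rep(1, 4L)
  f <- if (direction == "up") fc else 1 / fc
  v[(j + 1L):4L] <- f
  v
}

# stage multiplier vector for a temporal sign word
.pattern_multiplier <- function(label, step) {
  syms <- strsplit(label, "-", fixed = TRUE)[[1L]]
  f <- vapply(syms, function(s)
    switch(s, up = step, down = 1 / step, flat = 1), numeric(1L))
  cumprod(c(1, f))
}

.draw_counts <- function(mean_mat, cfg) {
  r <- cfg$replicates_per_stage
  mu <- mean_mat * r
  n <- length(mu)
  counts <- if (cfg$hard_planting) {
    round(mu)
  } else if (cfg$noise_model == "poisson") {
    matrix(stats::rpois(n, as.vector(mu)), nrow = nrow(mu), ncol = ncol(mu))
  } else {
    matrix(stats::rnbinom(n, mu = as.vector(mu), size = r / cfg$dispersion),
           nrow = nrow(mu), ncol = ncol(mu))
  }
  dimnames(counts) <- dimnames(mean_mat)
  counts
}

#' Generate a synthetic tri-omics dataset with planted ground truth
#'
#' Builds circRNA (RPM), miRNA (TPM) and mRNA (FPKM) matrices over the four
#' B-cell stages from planted per-stage mean counts, then draws counts under
#' the configured noise model (or writes the means through deterministically
#' under hard planting). Planted structure, in order: per-layer
#' stage-specific transcripts; ceRNA triplets (one per exclusive comparison
#' group slot, members four-fold DE in exactly that comparison with sponge
#' directionality); circRNA temporal patterns; extra DE transcripts. Planted
#' roles are drawn from the non-stage-specific pool, which must be large
#' enough (a configuration error names the violated bound otherwise).
#'
#' Normalized units: RPM/TPM = count / library_size x 1e6; FPKM =
#' count / (library_size/1e6 x length/1e3) with effective lengths drawn
#' uniformly in [500, 5000] nt.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (class `omics_dataset`: normalized
#'   matrices `circ`, `mirna`, `mrna`; count matrices `*_counts`;
#'   `lib_sizes`; `mrna_lengths`; `sequences`) and `truth` (class
#'   `ground_truth`: `expressed`, `specific_stage`, `pattern_labels`,
#'   `de_truth`, `planted_triplets`, `planted_sites`).
#' @export
generate_dataset <- function(config) {
  .stop_if(!inherits(config, "sim_config"),
           "`config` must come from simulation_config()")
  cfg <- config
  set.seed(cfg$rng_seed)
  stages <- b_cell_stages()
  comps <- adjacent_comparisons()$label

  lay <- list(
    circ  = .layer_structure(cfg$n_circ, "circ", cfg$frac_stage_specific[["circ"]]),
    mirna = .layer_structure(cfg$n_mirna, "mirna", cfg$frac_stage_specific[["mirna"]]),
    mrna  = .layer_structure(cfg$n_mrna, "mrna", cfg$frac_stage_specific[["mrna"]])
  )

  # how many planted (all-stage-expressed) transcripts each layer needs
  n_trip <- cfg$n_planted_triplets
  n_pat_total <- length(cfg$pattern_labels) * cfg$n_planted_patterns
  need <- c(
    circ  = 3L * n_trip + n_pat_total + 6L * cfg$n_planted_de,
    mirna = 3L * n_trip + 6L * cfg$n_planted_de,
    mrna  = 3L * n_trip + 6L * cfg$n_planted_de
  )
  pool <- lapply(names(lay), function(nm) {
    nonspec <- which(is.na(lay[[nm]]$specific))
    .stop_if(length(nonspec) < need[[nm]],
             "planting requires ", need[[nm]],
             " non-stage-specific transcripts in layer '", nm,
             "' but only ", length(nonspec), " are available; ",
             "reduce planting counts or frac_stage_specific")
    nonspec[sample.int(length(nonspec), need[[nm]])]
  })
  names(pool) <- names(lay)

  take <- function(nm, k) {
    idx <- pool[[nm]][seq_len(k)]
    pool[[nm]] <<- pool[[nm]][-seq_len(k)]
    idx
  }

  mult <- lapply(lay, function(l) {
    m <- (l$expressed) * 1
    dimnames(m) <- dimnames(l$expressed)
    m
  })
  mark_planted <- function(nm, idx) {
    lay[[nm]]$expressed[idx, ] <<- TRUE
    mult[[nm]][idx, ] <<- 1
  }
  de_truth <- list()
  record_de <- function(nm, id, comp_label, direction) {
    de_truth[[length(de_truth) + 1L]] <<- data.frame(
      layer = nm, transcript_id = id,
      comparison = comps,
      direction = ifelse(comps == comp_label, direction, "null"),
      stringsAsFactors = FALSE)
  }

  schemes <- c("circ_down_mir_up_mrna_down", "circ_up_mir_down_mrna_up")
  triplets <- list()
  for (j in seq_along(comps)) {
    if (n_trip == 0L) break
    idx_c <- take("circ", n_trip)
    idx_m <- take("mirna", n_trip)
    idx_g <- take("mrna", n_trip)
    mark_planted("circ", idx_c)
    mark_planted("mirna", idx_m)
    mark_planted("mrna", idx_g)
    for (t in seq_len(n_trip)) {
      scheme <- schemes[(t - 1L) %% 2L + 1L]
      d_circ <- if (scheme == schemes[1L]) "down" else "up"
      d_mir <- if (d_circ == "down") "up" else "down"
      ic <- idx_c[t]; im <- idx_m[t]; ig <- idx_g[t]
      mult$circ[ic, ] <- .step_multiplier(j, d_circ, cfg$de_fold_change)
      mult$mirna[im, ] <- .step_multiplier(j, d_mir, cfg$de_fold_change)
      mult$mrna[ig, ] <- .step_multiplier(j, d_circ, cfg$de_fold_change)
      record_de("circ", lay$circ$ids[ic], comps[j], d_circ)
      record_de("mirna", lay$mirna$ids[im], comps[j], d_mir)
      record_de("mrna", lay$mrna$ids[ig], comps[j], d_circ)
      triplets[[length(triplets) + 1L]] <- data.frame(
        circ_id = lay$circ$ids[ic], mirna_id = lay$mirna$ids[im],
        mrna_id = lay$mrna$ids[ig], comparison = comps[j],
        group = unname(.exclusive_group_of[comps[j]]), scheme = scheme,
        stringsAsFactors = FALSE)
    }
  }
  planted_triplets <- if (length(triplets) > 0) {
    do.call(rbind, triplets)
  } else {
    data.frame(circ_id = character(0), mirna_id = character(0),
               mrna_id = character(0), comparison = character(0),
               group = character(0), scheme = character(0),
               stringsAsFactors = FALSE)
  }

  pattern_labels <- stats::setNames(character(0), character(0))
  if (n_pat_total > 0L) {
    for (lab in cfg$pattern_labels) {
      idx <- take("circ", cfg$n_planted_patterns)
      mark_planted("circ", idx)
      pm <- .pattern_multiplier(lab, cfg$pattern_step)
      for (i in idx) mult$circ[i, ] <- pm
      pattern_labels[lay$circ$ids[idx]] <- lab
    }
  }

  if (cfg$n_planted_de > 0L) {
    for (nm in names(lay)) {
      for (j in seq_along(comps)) {
        for (dir in c("up", "down")) {
          idx <- take(nm, cfg$n_planted_de)
          mark_planted(nm, idx)
          sm <- .step_multiplier(j, dir, cfg$de_fold_change)
          for (i in idx) mult[[nm]][i, ] <- sm
          for (i in idx) record_de(nm, lay[[nm]]$ids[i], comps[j], dir)
        }
      }
    }
  }

  de_truth <- if (length(de_truth) > 0) {
    do.call(rbind, de_truth)
  } else {
    data.frame(layer = character(0), transcript_id = character(0),
               comparison = character(0), direction = character(0),
               stringsAsFactors = FALSE)
  }

  # per-transcript baseline count level (log-normal heterogeneity)
  means <- lapply(names(lay), function(nm) {
    n <- length(lay[[nm]]$ids)
    base <- cfg$baseline_mean * exp(stats::rnorm(n, 0, 0.5))
    mean_mat <- mult[[nm]] * base
    dimnames(mean_mat) <- dimnames(mult[[nm]])
    mean_mat
  })
  names(means) <- names(lay)

  counts <- lapply(means, .draw_counts, cfg = cfg)
  lib <- cfg$sequencing_depth * cfg$replicates_per_stage

  per_million <- function(m) sweep(m, 2L, lib, "/") * 1e6
  norm_source <- if (cfg$hard_planting) {
    lapply(means, function(m) m * cfg$replicates_per_stage)
  } else {
    counts
  }
  n_mrna <- length(lay$mrna$ids)
  mrna_len <- stats::setNames(round(stats::runif(n_mrna, 500, 5000)),
                              lay$mrna$ids)
  fpkm <- norm_source$mrna / outer(mrna_len / 1e3, lib / 1e6)
  dimnames(fpkm) <- dimnames(norm_source$mrna)

  sequences <- NULL
  planted_sites <- data.frame(
    mirna_id = character(0), target_id = character(0),
    target_kind = character(0), site_type = character(0),
    start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  if (cfg$with_sequences) {
    planted_int <- rbind(
      data.frame(mirna_id = planted_triplets$mirna_id,
                 target_id = planted_triplets$circ_id,
                 target_kind = "circRNA", stringsAsFactors = FALSE),
      data.frame(mirna_id = planted_triplets$mirna_id,
                 target_id = planted_triplets$mrna_id,
                 target_kind = "mRNA", stringsAsFactors = FALSE))
    if (cfg$sequence_scope == "all") {
      mir_ids <- lay$mirna$ids
      tgt_ids <- c(lay$circ$ids, lay$mrna$ids)
    } else {
      mir_ids <- unique(planted_triplets$mirna_id)
      tgt_ids <- unique(c(planted_triplets$circ_id, planted_triplets$mrna_id))
    }
    if (length(mir_ids) > 0 || length(tgt_ids) > 0) {
      gs <- generate_sequences(mir_ids, tgt_ids, planted_int,
                               rng_seed = NULL,
                               target_length = cfg$target_length,
                               mirna_length = cfg$mirna_length)
      sequences <- gs$sequences
      planted_sites <- gs$sites
    }
  }

  dataset <- list(
    circ = expression_matrix(per_million(norm_source$circ), "RPM"),
    mirna = expression_matrix(per_million(norm_source$mirna), "TPM"),
    mrna = expression_matrix(fpkm, "FPKM"),
    circ_counts = counts$circ,
    mirna_counts = counts$mirna,
    mrna_counts = counts$mrna,
    lib_sizes = lib,
    mrna_lengths = mrna_len,
    sequences = sequences,
    config = cfg
  )
  class(dataset) <- "omics_dataset"

  truth <- list(
    expressed = lapply(lay, `[[`, "expressed"),
    specific_stage = lapply(lay, `[[`, "specific"),
    pattern_labels = pattern_labels,
    de_truth = de_truth,
    planted_triplets = planted_triplets,
    planted_sites = planted_sites
  )
  class(truth) <- "ground_truth"

  list(dataset = dataset, truth = truth)
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf(
    "<omics_dataset> circ %d, mirna %d, mrna %d transcripts x 4 stages; %s\n",
    nrow(x$circ), nrow(x$mirna), nrow(x$mrna),
    if (is.null(x$sequences)) "no sequences"
    else sprintf("%d sequences", length(x$sequences))))
  invisible(x)
}

.random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

.seed6_of <- function(mirna_seq) revcomp_rna(substr(mirna_seq, 2L, 7L))

#' Generate sequences with planted canonical seed sites
#'
#' Draws random RNA sequences (uniform ACGU background) for the given
#' miRNA and target ids such that every planted (miRNA, target)
#' interaction's target carries at least one exact 8mer site for its miRNA
#' at a recorded position, while every non-planted pair carries no 6mer or
#' better site anywhere (rejection sampling, at most `max_attempts`
#' attempts per sequence before a hard error). miRNA seed regions are
#' resampled until mutually non-colliding, so rejection can terminate.
#'
#' @param mirna_ids,target_ids Character vectors of ids.
#' @param planted_interactions data.frame with columns `mirna_id`,
#'   `target_id` (optional `target_kind`); ids must be listed above.
#' @param rng_seed Optional integer seed (NULL continues the current
#'   random stream).
#' @param target_length,mirna_length Sequence lengths in nt
#'   (`mirna_length` >= 8).
#' @param max_attempts Rejection-sampling cap per sequence.
#' @return List with `sequences` (named character vector over
#'   miRNAs then targets) and `sites` (data.frame `mirna_id`, `target_id`,
#'   `target_kind`, `site_type`, `start`, `end`; 0-based half-open on the
#'   target).
#' @export
generate_sequences <- function(mirna_ids, target_ids,
                               planted_interactions = NULL,
                               rng_seed = NULL,
                               target_length = 300, mirna_length = 22,
                               max_attempts = 1000) {
  .stop_if(mirna_length < 8,
           "miRNA sequences must be at least 8 nt (empty or shorter miRNA not allowed)")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(planted_interactions)) {
    planted_interactions <- data.frame(mirna_id = character(0),
                                       target_id = character(0),
                                       stringsAsFactors = FALSE)
  }
  pi_df <- as.data.frame(planted_interactions)
  if (!"target_kind" %in% colnames(pi_df)) {
    pi_df$target_kind <- rep(NA_character_, nrow(pi_df))
  }
  .stop_if(!all(pi_df$mirna_id %in% mirna_ids),
           "planted interaction refers to unlisted miRNA id")
  .stop_if(!all(pi_df$target_id %in% target_ids),
           "planted interaction refers to unlisted target id")

  # miRNA sequences with mutually non-colliding seed regions: distinct
  # 6mer cores, and no core occurring inside another miRNA's 8mer site
  mirnas <- stats::setNames(character(length(mirna_ids)), mirna_ids)
  if (length(mirna_ids) > 0) {
    for (attempt in seq_len(max_attempts)) {
      mirnas[] <- vapply(mirna_ids, function(i) .random_rna(mirna_length), "")
      cores <- vapply(mirnas, .seed6_of, "")
      sites8 <- vapply(mirnas, function(s) .seed_site_strings(s)[["8mer"]], "")
      clash <- anyDuplicated(cores) > 0L
      if (!clash) {
        # a periodic seed whose core recurs inside its own 8mer site would
        # make target rejection unsatisfiable
        self_ok <- vapply(seq_along(cores), function(a)
          identical(.find_all_fixed(cores[a], sites8[a]), 2L), logical(1L))
        clash <- !all(self_ok)
      }
      if (!clash && length(mirnas) > 1L) {
        for (a in seq_along(cores)) {
          hit <- grepl(cores[a], sites8[-a], fixed = TRUE)
          if (any(hit)) { clash <- TRUE; break }
        }
      }
      if (!clash) break
      .stop_if(attempt == max_attempts,
               "could not sample non-colliding miRNA seed regions in ",
               max_attempts, " attempts")
    }
  }

  targets <- stats::setNames(character(length(target_ids)), target_ids)
  sites <- list()
  cores <- if (length(mirnas) > 0) {
    vapply(mirnas, .seed6_of, "")
  } else {
    character(0)
  }
  for (t in target_ids) {
    rows <- pi_df[pi_df$target_id == t, , drop = FALSE]
    planted_mirs <- rows$mirna_id
    .stop_if(8L * nrow(rows) > target_length,
             "target_length too short for ", nrow(rows),
             " planted site(s) on ", t)
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      seq_t <- .random_rna(target_length - 8L * nrow(rows))
      rec <- list()
      valid <- TRUE
      # insert one 8mer site per planted miRNA, never inside an earlier site
      for (ri in seq_len(nrow(rows))) {
        site <- .seed_site_strings(mirnas[[rows$mirna_id[ri]]])[["8mer"]]
        blocked <- unlist(lapply(rec, function(r) (r$start + 1L):(r$start + 7L)))
        allowed <- setdiff(0:nchar(seq_t), blocked)
        pos <- allowed[sample.int(length(allowed), 1L)]
        seq_t <- paste0(substr(seq_t, 1L, pos), site,
                        substr(seq_t, pos + 1L, nchar(seq_t)))
        rec <- lapply(rec, function(r) {
          if (r$start >= pos) r$start <- r$start + 8L
          r
        })
        rec[[length(rec) + 1L]] <- list(mirna_id = rows$mirna_id[ri],
                                        target_kind = rows$target_kind[ri],
                                        start = pos)
      }
      # planted cores may occur only inside their own recorded site
      # (the 6mer core sits at offset 1 within the 8mer site)
      for (m in names(cores)) {
        occ <- .find_all_fixed(cores[[m]], seq_t)   # 1-based starts
        if (m %in% planted_mirs) {
          own <- vapply(rec[vapply(rec, function(r) r$mirna_id == m,
                                   logical(1L))],
                        function(r) r$start + 2L, integer(1L))
          if (!setequal(occ, own) || length(occ) != length(own)) {
            valid <- FALSE; break
          }
        } else if (length(occ) > 0L) {
          valid <- FALSE; break
        }
      }
      if (valid) {
        targets[[t]] <- seq_t
        for (r in rec) {
          sites[[length(sites) + 1L]] <- data.frame(
            mirna_id = r$mirna_id, target_id = t,
            target_kind = r$target_kind, site_type = "8mer",
            start = r$start, end = r$start + 8L, stringsAsFactors = FALSE)
        }
        ok <- TRUE
        break
      }
    }
    .stop_if(!ok, "rejection sampling failed after ", max_attempts,
             " attempts for target ", t)
  }
  sites_df <- if (length(sites) > 0) {
    do.call(rbind, sites)
  } else {
    data.frame(mirna_id = character(0), target_id = character(0),
               target_kind = character(0), site_type = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  }
  list(sequences = c(mirnas, targets), sites = sites_df)
}

# all 1-based start positions of fixed `pattern` in `text` (overlapping)
.find_all_fixed <- function(pattern, text) {
  k <- nchar(pattern); n <- nchar(text)
  if (k > n) return(integer(0))
  starts <- seq_len(n - k + 1L)
  starts[substring(text, starts, starts + k - 1L) == pattern]
}
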