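#' Waveform specification for synthetic islet traces
#'
#' Phenomenological description of one islet's response to one stimulus
#' segment. Oscillating archetypes are logistic-edged (square-like) waves so
#' that the generator's duty cycle and the 50%-of-amplitude active duration
#' agree; `plateau` holds `baseline + amplitude` for the whole segment and
#' `silent` holds `baseline`. `mixed` is the sum of a slow and a fast square
#' wave with a 2:1 amplitude ratio (fast ripple riding on slow bursts).
#'
#' @param archetype One of `"slow"`, `"fast"`, `"plateau"`, `"silent"`,
#'   `"mixed"`.
#' @param period Oscillation period in minutes (slow component for `mixed`;
#'   ignored for `plateau`/`silent`). If `NA`, a period is drawn when the trace
#'   is generated: uniform on \[2, 10\] min for `slow`, on \[0.5, 2) min for
#'   `fast`/`mixed`.
#' @param duty Active-phase share of the period, in (0, 1).
#' @param baseline Resting ratio level (ratio units).
#' @param amplitude Burst height above baseline (ratio units, >= 0).
#' @param drift_slope Linear drift, ratio units per minute.
#' @param noise_sd I.i.d. Gaussian noise SD on the ratio (>= 0).
#' @param period_fast Fast-component period for `mixed`, minutes (default
#'   `period / 6`).
#' @param edge_width Logistic edge width in minutes; default is a quarter of
#'   the sampling interval at generation time (sharp, near-step edges).
#' @param seed Integer seed; fixed seed gives a bitwise-identical trace.
#' @return A list of class `wave_spec`.
#' @export
wave_spec <- function(archetype = c("slow", "fast", "plateau", "silent", "mixed"),
                      period = NA_real_, duty = 0.5, baseline = 1,
                      amplitude = 0.5, drift_slope = 0, noise_sd = 0,
                      period_fast = NULL, edge_width = NULL, seed = NULL) {
  archetype <- match.arg(archetype)
  if (!is.na(period) && period <= 0) stop("period must be positive")
  if (duty <= 0 || duty >= 1) stop("duty must lie in (0, 1)")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(archetype = archetype, period = period, duty = duty,
                 baseline = baseline, amplitude = amplitude,
                 drift_slope = drift_slope, noise_sd = noise_sd,
                 period_fast = period_fast, edge_width = edge_width,
                 seed = seed),
            class = "wave_spec")
}

# Logistic-edged periodic square pulse train on phase grid; 0.5 exactly at the
# active/silent boundaries, so the fraction of time above midline equals duty.
square_component <- function(tt, period, duty, edge_width) {
  p <- (tt / period) %% 1
  d <- ifelse(p < duty, pmin(p, duty - p), -pmin(p - duty, 1 - p)) * period
  stats::plogis(d / edge_width)
}

#' Generate one synthetic trace segment
#'
#' @param spec A [wave_spec()].
#' @param segment_length Segment length in minutes.
#' @param sampling_interval Sampling interval in minutes (default 0.1 = 6 s).
#' @param t0 Time of the first frame (minutes); the waveform phase is zero at
#'   `t0`.
#' @param islet_id,strain,sex,animal Metadata passed to [islet_trace()].
#' @return An [islet_trace()] with `segment_length / sampling_interval` frames.
#' @export
make_trace <- function(spec, segment_length = 40, sampling_interval = 0.1,
                       t0 = 0, islet_id = "synthetic",
                       strain = NA_character_, sex = NA_character_,
                       animal = NA_character_) {
  stopifnot(inherits(spec, "wave_spec"))
  n <- round(segment_length / sampling_interval)
  if (abs(n * sampling_interval - segment_length) > 1e-6 * segment_length) {
    stop("segment_length must be an integer number of sampling intervals")
  }
  tt <- (seq_len(n) - 1L) * sampling_interval
  osc <- spec$archetype %in% c("slow", "fast", "mixed")
  with_preserved_seed(spec$seed, {
    period <- spec$period
    if (osc && is.na(period)) {
      period <- switch(spec$archetype,
                       slow = stats::runif(1, 2, 10),
                       stats::runif(1, 0.5, 2))
    }
    if (osc && period <= 2 * sampling_interval) {
      stop("period must exceed twice the sampling interval for oscillating archetypes")
    }
    w <- spec$edge_width %||% (sampling_interval / 4)
    s <- switch(spec$archetype,
      plateau = rep(1, n),
      silent  = rep(0, n),
      slow    = ,
      fast    = square_component(tt, period, spec$duty, w),
      mixed   = {
        pf <- spec$period_fast %||% (period / 6)
        square_component(tt, period, spec$duty, w) +
          0.5 * square_component(tt, pf, spec$duty, w)
      })
    v <- spec$baseline + spec$amplitude * s + spec$drift_slope * tt
    if (spec$noise_sd > 0) v <- v + stats::rnorm(n, 0, spec$noise_sd)
    islet_trace(time = t0 + tt, values = v, islet_id = islet_id,
                strain = strain, sex = sex, animal = animal)
  })
}

#' Cohort specification for the synthetic generator
#'
#' @param strains Character vector of strain labels.
#' @param sexes Character vector of sex labels.
#' @param animals_per_group Animals per strain-by-sex group.
#' @param islets_per_animal Islets imaged per animal.
#' @param archetype_map Named list: `strain -> named list(segment label ->
#'   wave_spec)`. Must cover every strain and every segment label.
#' @param segment_labels Stimulus segment labels, in order.
#' @param sampling_interval Minutes between frames (default 0.1 = 6 s).
#' @param segment_length Minutes per segment (default 40).
#' @param seed Root seed; per-islet seeds are derived from it by counter so any
#'   subset regenerates identically.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(strains, sexes = c("F", "M"), animals_per_group = 3,
                        islets_per_animal = 5, archetype_map,
                        segment_labels = c("8G", "8G/QLA", "8G/QLA/GIP", "2G"),
                        sampling_interval = 0.1, segment_length = 40,
                        seed = 1L) {
  n <- segment_length / sampling_interval
  if (abs(n - round(n)) > 1e-9) {
    stop("segment_length / sampling_interval must be an integer frame count")
  }
  missing_strain <- setdiff(strains, names(archetype_map))
  if (length(missing_strain)) {
    stop("archetype_map lacks strains: ", paste(missing_strain, collapse = ", "))
  }
  for (s in strains) {
    missing_seg <- setdiff(segment_labels, names(archetype_map[[s]]))
    if (length(missing_seg)) {
      stop("archetype_map for strain ", s, " lacks segments: ",
           paste(missing_seg, collapse = ", "))
    }
  }
  structure(list(strains = strains, sexes = sexes,
                 animals_per_group = animals_per_group,
                 islets_per_animal = islets_per_animal,
                 archetype_map = archetype_map,
                 segment_labels = segment_labels,
                 sampling_interval = sampling_interval,
                 segment_length = segment_length, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default strain-archetype map
#'
#' Emulates the qualitative strain phenotypes of the eight Collaborative Cross
#' founders: classical strains (A/J, B6, 129) slow in the stimulatory
#' segments; wild-derived strains (CAST, PWK, WSB) fast in 8G and plateaued
#' under amino acids and GIP; NOD mixed slow-plus-fast under amino acids; NZO
#' (diabetic-like) silent in 8G with plateau responses afterwards; every strain
#' silent at basal 2 mM glucose. Amplitude/noise levels are generator defaults,
#' not calibrated to any measured cohort.
#'
#' @param noise_sd Gaussian noise SD applied to every segment.
#' @param drift_slope Linear drift (ratio units/min) applied to every segment.
#' @return Named list suitable for [cohort_spec()]'s `archetype_map`.
#' @export
default_archetype_map <- function(noise_sd = 0.01, drift_slope = -0.002) {
  w <- function(arch, period = NA_real_, duty = 0.5, amplitude = 0.5) {
    wave_spec(arch, period = period, duty = duty, baseline = 1,
              amplitude = amplitude, drift_slope = drift_slope,
              noise_sd = noise_sd)
  }
  classical <- list("8G" = w("slow", 4, 0.4), "8G/QLA" = w("slow", 5, 0.6),
                    "8G/QLA/GIP" = w("slow", 4, 0.5), "2G" = w("silent"))
  wild <- list("8G" = w("fast", 1, 0.3), "8G/QLA" = w("plateau"),
               "8G/QLA/GIP" = w("plateau"), "2G" = w("silent"))
  nod <- list("8G" = w("slow", 5, 0.4), "8G/QLA" = w("mixed", 6, 0.6),
              "8G/QLA/GIP" = w("mixed", 6, 0.6), "2G" = w("silent"))
  nzo <- list("8G" = w("silent"), "8G/QLA" = w("plateau", amplitude = 0.6),
              "8G/QLA/GIP" = w("plateau", amplitude = 0.4), "2G" = w("silent"))
  list("A/J" = classical, "B6" = classical, "129" = classical,
       "NOD" = nod, "NZO" = nzo,
       "CAST" = wild, "PWK" = wild, "WSB" = wild)
}

#' Generate a synthetic cohort of islet traces
#'
#' Builds one full-length trace per islet by concatenating per-segment waves
#' from the strain's archetype map; waveform phase restarts at each solution
#' transition. Deterministic: the whole cohort is a pure function of its spec,
#' including the seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `islet_cohort` with elements `traces` (list of
#'   [islet_trace()]), `schedule` (a [segment_schedule()]), and `spec`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labs <- spec$segment_labels
  starts <- (seq_along(labs) - 1L) * spec$segment_length
  sched <- segment_schedule(labs, starts, starts + spec$segment_length)
  traces <- list()
  counter <- 0L
  for (strain in spec$strains) {
    for (sex in spec$sexes) {
      for (a in seq_len(spec$animals_per_group)) {
        animal <- paste(strain, sex, a, sep = "_")
        for (i in seq_len(spec$islets_per_animal)) {
          counter <- counter + 1L
          islet_seed <- derive_seed(spec$seed, counter)
          id <- paste(strain, sex, a, i, sep = "_")
          segs <- lapply(seq_along(labs), function(k) {
            ws <- spec$archetype_map[[strain]][[labs[k]]]
            ws$seed <- derive_seed(islet_seed, k)
            make_trace(ws, segment_length = spec$segment_length,
                       sampling_interval = spec$sampling_interval,
                       t0 = starts[k], islet_id = id,
                       strain = strain, sex = sex, animal = animal)
          })
          traces[[id]] <- islet_trace(
            time = unlist(lapply(segs, `[[`, "time")),
            values = unlist(lapply(segs, `[[`, "values")),
            islet_id = id, strain = strain, sex = sex, animal = animal)
        }
      }
    }
  }
  structure(list(traces = traces, schedule = sched, spec = spec),
            class = "islet_cohort")
}

#' @export
print.islet_cohort <- function(x, ...) {
  cat(sprintf("<islet_cohort> %d traces, %d segments (%s)\n",
              length(x$traces), nrow(x$schedule),
              paste(x$schedule$label, collapse = ", ")))
  invisible(x)
}

#' Synthesize an animal-by-protein abundance matrix with planted correlations
#'
#' Each planted protein is the named parameter's Z-score scaled and mixed with
#' Gaussian noise so the expected Pearson correlation with that parameter
#' equals `target_r` (mixing weight `t = |r| * noise_sd / sqrt(1 - r^2)`, so
#' `r = t / sqrt(t^2 + noise_sd^2)`). A protein planted against several
#' parameters receives the sum of the per-parameter terms; note that the
#' per-pair mixing weights are derived under parameter independence, so a
#' protein planted on several mutually correlated parameters realises
#' correlations above the individual targets, while planting large targets on
#' several independent parameters is infeasible (the squared correlations to
#' independent targets sum to at most one) and realises proportionally shrunk
#' values. Non-planted
#' proteins are independent `N(0, noise_sd)` noise. With `noise_sd = 0` a
#' planted column is an exact (sign-preserving) copy of the parameter Z-score,
#' i.e. sample `|r| = 1`.
#'
#' @param animal_params Data frame with key columns (any of `strain`, `sex`,
#'   `animal`) plus numeric parameter columns.
#' @param n_proteins Total protein count (planted plus nulls).
#' @param planted Data frame with columns `protein`, `parameter`, `target_r`,
#'   or `NULL` for none.
#' @param noise_sd Noise SD in abundance units.
#' @param seed Integer seed.
#' @return Data frame: the key columns of `animal_params` followed by one
#'   numeric column per protein.
#' @export
make_protein_matrix <- function(animal_params, n_proteins, planted = NULL,
                                noise_sd = 1, seed = 1L) {
  keys <- intersect(c("strain", "sex", "animal"), names(animal_params))
  n <- nrow(animal_params)
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("protein", "parameter", "target_r") %in% names(planted)))
    if (any(abs(planted$target_r) > 1)) stop("|target_r| must be <= 1")
    bad <- setdiff(planted$parameter, names(animal_params))
    if (length(bad)) stop("planted parameters not in animal_params: ",
                          paste(bad, collapse = ", "))
  }
  planted_ids <- unique(planted$protein)
  if (length(planted_ids) > n_proteins) stop("more planted proteins than n_proteins")
  null_ids <- sprintf("null_%03d", seq_len(n_proteins - length(planted_ids)))
  ids <- c(planted_ids, null_ids)
  with_preserved_seed(seed, {
    cols <- lapply(ids, function(id) {
      rows <- which(planted$protein == id)
      if (length(rows) == 0L) return(stats::rnorm(n, 0, noise_sd))
      v <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
      for (j in rows) {
        z <- zscore(animal_params[[planted$parameter[j]]])
        r <- planted$target_r[j]
        t <- if (noise_sd == 0 || abs(r) == 1) 1 else abs(r) * noise_sd / sqrt(1 - r^2)
        v <- v + sign(r) * t * z
      }
      v
    })
    names(cols) <- ids
    out <- cbind(animal_params[keys], as.data.frame(cols, check.names = FALSE,
                                                    optional = TRUE))
    names(out) <- c(keys, ids)
    out
  })
}

#' Generate toy genomic fixtures (genes, SNPs, loop anchors)
#'
#' Builds non-overlapping genes on a single toy chromosome, SNPs placed at
#' controlled distances from gene bounds (inside the body, inside the 100-kbp
#' flanking window, beyond it, or uniform), and promoter-to-distal loop
#' contacts. Gene coordinates are BED-style 0-based half-open; SNP positions
#' are 1-based.
#'
#' @param n_genes,n_snps,n_loops Non-negative counts.
#' @param seed Integer seed; fixtures are deterministic per seed.
#' @param chrom Toy chromosome name.
#' @return List with data frames `genes` (`chrom,start,end,gene_id,score,
#'   strand`), `snps` (`chrom,pos,rsid,pvalue,trait`), `loops`
#'   (`chrom1,start1,end1,chrom2,start2,end2`).
#' @export
make_genomic_fixtures <- function(n_genes, n_snps, n_loops, seed = 1L,
                                  chrom = "chrT") {
  stopifnot(n_genes >= 0, n_snps >= 0, n_loops >= 0)
  with_preserved_seed(seed, {
    widths <- if (n_genes) round(stats::runif(n_genes, 2e4, 6e4)) else integer()
    gaps <- if (n_genes) round(stats::runif(n_genes, 2.6e5, 4e5)) else integer()
    starts <- cumsum(gaps) + cumsum(c(0, widths[-length(widths)]))
    genes <- data.frame(chrom = rep(chrom, n_genes), start = starts,
                        end = starts + widths,
                        gene_id = sprintf("GENE%03d", seq_len(n_genes)),
                        score = 0L,
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    snps <- data.frame(chrom = character(), pos = integer(), rsid = character(),
                       pvalue = numeric(), trait = character(),
                       stringsAsFactors = FALSE)
    if (n_snps > 0 && n_genes > 0) {
      g <- sample(n_genes, n_snps, replace = TRUE)
      kind <- sample(c("body", "window", "outside", "anywhere"), n_snps,
                     replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.2))
      pos <- integer(n_snps)
      for (k in seq_len(n_snps)) {
        gs <- genes$start[g[k]]; ge <- genes$end[g[k]]
        pos[k] <- switch(kind[k],
          body = round(stats::runif(1, gs + 1, ge)),
          window = {
            off <- round(stats::runif(1, 1, 99000))
            if (stats::runif(1) < 0.5) gs - off + 1L else ge + off
          },
          outside = ge + 100001L + round(stats::runif(1, 0, 5e4)),
          anywhere = round(stats::runif(1, 1, max(genes$end) + 2e5)))
      }
      sig <- stats::runif(n_snps) < 0.7
      pval <- ifelse(sig, 10^-stats::runif(n_snps, 8.5, 20),
                     10^-stats::runif(n_snps, 2, 7.5))
      snps <- data.frame(chrom = chrom, pos = pmax(1L, as.integer(pos)),
                         rsid = sprintf("rs%06d", seq_len(n_snps)),
                         pvalue = pval,
                         trait = sample(glycemic_traits(), n_snps, replace = TRUE),
                         stringsAsFactors = FALSE)
    }
    loops <- data.frame(chrom1 = character(), start1 = integer(),
                        end1 = integer(), chrom2 = character(),
                        start2 = integer(), end2 = integer(),
                        stringsAsFactors = FALSE)
    if (n_loops > 0 && n_genes > 0) {
      g <- sample(n_genes, n_loops, replace = TRUE)
      tss <- ifelse(genes$strand[g] == "+", genes$start[g], genes$end[g])
      dist <- round(stats::runif(n_loops, 2e5, 6e5)) *
        sample(c(-1L, 1L), n_loops, replace = TRUE)
      a2 <- pmax(0L, as.integer(tss + dist))
      loops <- data.frame(chrom1 = chrom, start1 = pmax(0L, as.integer(tss - 2000L)),
                          end1 = as.integer(tss + 2000L),
                          chrom2 = chrom, start2 = a2, end2 = a2 + 10000L,
                          stringsAsFactors = FALSE)
    }
    list(genes = genes, snps = snps, loops = loops)
  })
}

#' Deterministic three-gene demonstration fixture for SNP-to-gene assignment
#'
#' One gene with a significant SNP just inside the 100-kbp flanking window (and
#' a boundary-significance SNP in its body that the strict p-value filter
#' drops), one gene reachable only through a promoter-capture loop to a distal
#' SNP-bearing anchor, and one gene whose nearest significant SNP lies just
#' beyond the window. Under the default cutoffs exactly the first two genes are
#' nominated, via the window and loop routes respectively.
#'
#' @return List with `genes`, `snps`, `loops` data frames as in
#'   [make_genomic_fixtures()].
#' @export
gwas_demo_fixture <- function() {
  genes <- data.frame(
    chrom = "chrT",
    start = c(1000000L, 3000000L, 6000000L),
    end = c(1050000L, 3040000L, 6040000L),
    gene_id = c("GENE_WINDOW", "GENE_LOOP", "GENE_FAR"),
    score = 0L,
    strand = c("+", "+", "+"),
    stringsAsFactors = FALSE)
  snps <- data.frame(
    chrom = "chrT",
    pos = c(1000000L - 99999L,  # 99,999 bp upstream of GENE_WINDOW: in window
            1020000L,           # in GENE_WINDOW body but p = 1e-8: filtered out
            3540005L,           # inside GENE_LOOP's distal loop anchor
            6040000L + 100001L),# 100,001 bp beyond GENE_FAR: out of window
    rsid = c("rs_window", "rs_body_boundary", "rs_loop", "rs_far"),
    pvalue = c(1e-10, 1e-8, 1e-9, 1e-12),
    trait = c("fasting glucose", "T2D", "T2D", "HbA1c"),
    stringsAsFactors = FALSE)
  loops <- data.frame(
    chrom1 = "chrT", start1 = 2998000L, end1 = 3002000L,  # GENE_LOOP promoter
    chrom2 = "chrT", start2 = 3535000L, end2 = 3545000L,  # distal anchor
    stringsAsFactors = FALSE)
  list(genes = genes, snps = snps, loops = loops)
}

#' Write genomic fixtures to BED / TSV / BEDPE files
#'
#' @param fixtures List as returned by [make_genomic_fixtures()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`genes.bed`, `snps.tsv`,
#'   `loops.bedpe`).
#' @export
write_genomic_fixtures <- function(fixtures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genes = file.path(dir, "genes.bed"),
             snps = file.path(dir, "snps.tsv"),
             loops = file.path(dir, "loops.bedpe"))
  write_genes_bed(fixtures$genes, paths["genes"])
  write_snps_tsv(fixtures$snps, paths["snps"])
  write_loops_bedpe(fixtures$loops, paths["loops"])
  invisible(paths)
}
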