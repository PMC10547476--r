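# Independent oracles kept deliberately naive: plain loops and direct
# definitions, no interval indexes and no reuse of package internals.

# All-pairs window-assignment scan (0-based half-open gene coordinates,
# 1-based SNP positions), the oracle for assign_window(): every SNP is checked
# against every gene directly, no interval index.
brute_force_window <- function(snps, genes, window_kbp = 100) {
  w <- window_kbp * 1000
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    pos0 <- snps$pos[i] - 1
    hit <- snps$chrom[i] == genes$chrom &
      pos0 >= genes$start - w & pos0 < genes$end + w
    if (!any(hit)) next
    body <- pos0 >= genes$start[hit] & pos0 < genes$end[hit]
    out[[i]] <- data.frame(gene_id = genes$gene_id[hit],
                           rsid = snps$rsid[i],
                           route = ifelse(body, "body", "window"),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), rsid = character(),
                      route = character(), stringsAsFactors = FALSE)
  }
  out[order(out$gene_id, out$rsid), , drop = FALSE]
}

# Count supra-threshold runs of a vector by direct scan (oracle for pulse
# counting).
brute_force_run_count <- function(v, threshold) {
  above <- v >= threshold
  sum(above & !c(FALSE, above[-length(above)]))
}

# Simple four-segment test cohort: one slow, one fast strain.
two_strain_cohort <- function(noise_sd = 0, seed = 11, animals = 1, islets = 2) {
  w <- function(arch, period, duty) {
    wave_spec(arch, period = period, duty = duty, baseline = 1,
              amplitude = 0.5, noise_sd = noise_sd)
  }
  amap <- list(
    SLOW = list("8G" = w("slow", 4, 0.4), "8G/QLA" = w("slow", 5, 0.6),
                "8G/QLA/GIP" = w("slow", 4, 0.5), "2G" = wave_spec("silent")),
    FAST = list("8G" = w("fast", 1, 0.3), "8G/QLA" = wave_spec("plateau"),
                "8G/QLA/GIP" = wave_spec("plateau"), "2G" = wave_spec("silent")))
  make_cohort(cohort_spec(c("SLOW", "FAST"), c("F", "M"),
                          animals_per_group = animals,
                          islets_per_animal = islets,
                          archetype_map = amap, seed = seed))
}

# 16-animal focus-parameter table mirroring the real correlation structure:
# the three silent-duration traits are near-duplicates of one another
# (pairwise correlation about rho), while basal average and the 8G
# active/pulse durations are independent (see the methods vignette).
focus_param_table <- function(n_animals = 16, seed = 1, rho = 0.85) {
  focus <- default_focus_params()
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tab <- data.frame(strain = rep(sprintf("S%d", 1:8), each = 2),
                    sex = rep(c("F", "M"), 8),
                    animal = sprintf("A%02d", seq_len(n_animals)),
                    stringsAsFactors = FALSE)
  for (f in focus[1:3]) tab[[f]] <- rnorm(n_animals)
  shared <- rnorm(n_animals)  # latent silent-duration factor
  for (f in focus[4:6]) {
    tab[[f]] <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n_animals)
  }
  tab
}

# Silent-duration trio of the focus set (the planted targets in the
# regulator-recovery fixtures).
silent_focus_params <- function() default_focus_params()[4:6]
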