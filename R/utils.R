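#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Counter-based child-seed derivation so any subset of a cohort is reproducible
# on its own. Stays below 2^31 - 1.
derive_seed <- function(root_seed, counter) {
  as.integer((as.double(root_seed) %% 2147483629 + 104729 * as.double(counter)) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Glycemia-related GWAS trait vocabulary
#'
#' Controlled list of glycemic-trait labels accepted in SNP tables: fasting
#' hormone measures, glucose measures, tolerance-test readouts, and diabetes
#' risk categories (BMI-adjusted variants of each term are also accepted
#' upstream by suffix, but are not enumerated here).
#'
#' @return Character vector of trait labels.
#' @export
glycemic_traits <- function() {
  c("insulin", "proinsulin", "C-peptide", "fasting glc-BMI interaction",
    "fasting glucose", "random glucose", "HbA1c",
    "2 hr glucose", "2 hr insulin", "2 hr C-peptide",
    "acute insulin response", "T1D", "T2D")
}
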