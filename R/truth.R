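#' Construct ground-truth binding occupancies and stress retentions
#'
#' Defines, per study transcript, how a scanning initiation factor distributes
#' its occupancy between the 5' region (5'UTR + first 150 nt of CDS) and the
#' rest of the transcript body, and, per condition, what fraction of each
#' component survives stress. Two archetypes are planted:
#'
#' * eIF4B-like transcripts concentrate `fivep_share` (default 0.9) of their
#'   occupancy in the 5' region;
#' * Ded1-like ("pervasive") transcripts have the shares swapped, so
#'   downstream binding is at least as strong as 5' binding.
#'
#' A stress-invariant rRNA-like background holds `background_share` of the
#' control library's occupancy mass, mirroring real initiation-factor CRAC
#' libraries in which rRNA reads dominate. Within each condition, expected
#' read probabilities are the renormalized products
#' abundance x (fivep_weight x fivep_retention + pervasive_weight x
#' pervasive_retention), plus the constant background mass.
#'
#' @param bundle a `genome_bundle`; must contain study transcripts.
#' @param factor_profile list with `fivep_share` (share of occupancy in the
#'   5' region for eIF4B-like transcripts, in (0.5, 1]) and
#'   `pervasive_transcript_fraction` (fraction of study transcripts made
#'   Ded1-like).
#' @param stress_model data.frame with columns `condition`,
#'   `fivep_retention`, `pervasive_retention`, all retentions in \[0, 1\].
#'   `control` and `mock` rows with retention 1 are added when absent.
#' @param abundance optional named per-transcript relative mRNA abundances;
#'   default log-normal (sdlog 0.5) copy numbers.
#' @param decay_model optional named list: condition -> multipliers
#'   `c(RP=, RiBi=, other=)` applied to abundances in that condition.
#' @param background_share fraction of control library occupancy attributed
#'   to the rRNA-like background (0 disables; requires `bundle$rrna`
#'   when > 0).
#' @param seed integer seed (used to pick the pervasive transcript set and
#'   abundances).
#'
#' @return A `binding_truth`: list with `transcripts` (id, fivep_weight,
#'   pervasive_weight), `conditions`, `abundance` (matrix transcripts x
#'   conditions) and `background_share`.
#' @export
make_binding_truth <- function(bundle,
                               factor_profile = list(
                                 fivep_share = 0.9,
                                 pervasive_transcript_fraction = 0),
                               stress_model = NULL,
                               abundance = NULL,
                               decay_model = NULL,
                               background_share = 0.9,
                               seed = 1) {
  tx <- bundle$transcripts[bundle$transcripts$species == "study", ]
  if (nrow(tx) == 0) stopf("bundle contains no study transcripts")
  fs <- factor_profile$fivep_share %||% 0.9
  pf <- factor_profile$pervasive_transcript_fraction %||% 0
  if (fs <= 0.5 || fs > 1)
    stopf("fivep_share must be in (0.5, 1]")
  if (pf < 0 || pf > 1) stopf("pervasive_transcript_fraction in [0,1]")
  if (background_share < 0 || background_share >= 1)
    stopf("background_share must be in [0, 1)")
  if (background_share > 0 && is.null(bundle$rrna))
    stopf("background_share > 0 requires an rRNA locus in the bundle")

  if (is.null(stress_model))
    stress_model <- data.frame(condition = character(0),
                               fivep_retention = numeric(0),
                               pervasive_retention = numeric(0))
  if (!all(c("condition", "fivep_retention",
             "pervasive_retention") %in% names(stress_model)))
    stopf("stress_model needs condition/fivep_retention/pervasive_retention")
  if (any(stress_model$fivep_retention < 0 | stress_model$fivep_retention > 1) ||
      any(stress_model$pervasive_retention < 0 |
          stress_model$pervasive_retention > 1))
    stopf("retentions must lie in [0, 1]")
  for (ref in c("control", "mock")) {
    if (!ref %in% stress_model$condition)
      stress_model <- rbind(stress_model,
                            data.frame(condition = ref, fivep_retention = 1,
                                       pervasive_retention = 1))
  }

  with_rng(seed, {
    n <- nrow(tx)
    n_perv <- round(pf * n)
    perv <- rep(FALSE, n)
    if (n_perv > 0) perv[sample(n, n_perv)] <- TRUE
    weights <- data.frame(
      id = tx$id,
      pervasive = perv,
      fivep_weight = ifelse(perv, 1 - fs, fs),
      pervasive_weight = ifelse(perv, fs, 1 - fs),
      stringsAsFactors = FALSE)

    if (is.null(abundance)) {
      abundance <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
      names(abundance) <- tx$id
    } else {
      abundance <- abundance[tx$id]
      if (anyNA(abundance)) stopf("abundance must cover every study transcript")
    }
    conds <- stress_model$condition
    ab <- matrix(rep(abundance, length(conds)), ncol = length(conds),
                 dimnames = list(tx$id, conds))
    if (!is.null(decay_model)) {
      for (cond in names(decay_model)) {
        if (!cond %in% conds) next
        mult <- decay_model[[cond]]
        m <- unname(mult[match(tx$regulon, names(mult))])
        m[is.na(m)] <- mult[["other"]] %||% 1
        ab[, cond] <- ab[, cond] * m
      }
    }

    structure(list(transcripts = weights,
                   conditions = stress_model,
                   abundance = ab,
                   background_share = background_share),
              class = "binding_truth")
  })
}

## Expected CRAC read-sampling probabilities for one condition.
## Returns list(tx = data.frame(id, prob, fivep_prob, pervasive_prob),
## background = scalar prob). Probabilities sum to 1.
crac_read_probs <- function(truth, condition) {
  sm <- truth$conditions
  row <- sm[sm$condition == condition, ]
  if (nrow(row) != 1) stopf("unknown condition '%s'", condition)
  w <- truth$transcripts
  a <- truth$abundance[w$id, condition]
  fmass <- a * w$fivep_weight * row$fivep_retention
  pmass <- a * w$pervasive_weight * row$pervasive_retention
  ## background sized against the *control* mRNA mass so that it holds
  ## background_share of the control library and is invariant to stress
  a0 <- truth$abundance[w$id, "control"]
  m0 <- sum(a0 * (w$fivep_weight + w$pervasive_weight))
  bmass <- if (truth$background_share > 0)
    truth$background_share / (1 - truth$background_share) * m0 else 0
  tot <- sum(fmass) + sum(pmass) + bmass
  list(tx = data.frame(id = w$id,
                       fivep_prob = fmass / tot,
                       pervasive_prob = pmass / tot,
                       prob = (fmass + pmass) / tot,
                       stringsAsFactors = FALSE),
       background = bmass / tot)
}
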