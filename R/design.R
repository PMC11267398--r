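#' Generate the paired study design
#'
#' Builds the fish metadata table for a paired dominant/subordinate design:
#' one dominant and one subordinate female per social group, housed in
#' adjacent chambers, with the 24 h social and isolation baseline blocks in
#' randomized order. The recovery condition of a pair always matches the
#' treatment of its second baseline block, so the number of social-recovery
#' pairs fixes the block order: a pair recovering in visual contact ran
#' isolation first.
#'
#' Dominant body mass is lognormal; the subordinate of a pair is
#' size-matched to its dominant up to a small lognormal deviation,
#' reflecting selection of the largest subordinate female from each group.
#'
#' @param n_pairs number of dominant-subordinate pairs (default 16).
#' @param n_social_recovery number of pairs recovering in visual contact
#'   (default 9; the remainder recover in isolation).
#' @param seed integer seed for mass draws and order randomization.
#' @param mass_meanlog,mass_sdlog lognormal parameters for dominant mass (g).
#' @param pair_mass_ratio_sdlog lognormal sd of the subordinate:dominant
#'   mass ratio (mean ratio 1).
#' @param chamber_volume_l chamber volume (litres), identical for all fish.
#' @return a `data.frame` with columns `fish_id`, `pair_id`, `status`
#'   (`"dominant"`/`"subordinate"`), `mass_g`, `chamber_volume_l`,
#'   `treatment_order` (`"social-first"`/`"isolation-first"`) and
#'   `recovery_condition` (`"social"`/`"isolation"`).
#' @export
#' @examples
#' d <- study_design(seed = 1)
#' table(d$status, d$recovery_condition)
study_design <- function(n_pairs = 16,
                         n_social_recovery = 9,
                         seed = 1,
                         mass_meanlog = log(8.5),
                         mass_sdlog = 0.15,
                         pair_mass_ratio_sdlog = 0.05,
                         chamber_volume_l = 0.5) {
  stopifnot(n_pairs >= 1, n_social_recovery >= 0, n_social_recovery <= n_pairs)
  with_seed(substream_seed(seed, "design"), {
    pair_id <- sprintf("P%02d", seq_len(n_pairs))
    dom_mass <- rlnorm(n_pairs, mass_meanlog, mass_sdlog)
    sub_mass <- dom_mass * rlnorm(n_pairs, 0, pair_mass_ratio_sdlog)
    soc_rec <- sort(sample(n_pairs, n_social_recovery))
    recovery <- ifelse(seq_len(n_pairs) %in% soc_rec, "social", "isolation")
    order <- ifelse(recovery == "social", "isolation-first", "social-first")
    out <- data.frame(
      fish_id = as.vector(rbind(paste0(pair_id, "_D"), paste0(pair_id, "_S"))),
      pair_id = rep(pair_id, each = 2),
      status = rep(c("dominant", "subordinate"), n_pairs),
      mass_g = as.vector(rbind(dom_mass, sub_mass)),
      chamber_volume_l = chamber_volume_l,
      treatment_order = rep(order, each = 2),
      recovery_condition = rep(recovery, each = 2),
      stringsAsFactors = FALSE)
    validate_design(out)
    out
  })
}

validate_design <- function(design) {
  req <- c("fish_id", "pair_id", "status", "mass_g", "chamber_volume_l",
           "treatment_order", "recovery_condition")
  miss <- setdiff(req, names(design))
  if (length(miss)) {
    config_error("configuration error: design is missing columns: %s",
                 paste(miss, collapse = ", "))
  }
  tab <- table(design$pair_id, design$status)
  if (!all(dim(tab) == c(length(unique(design$pair_id)), 2)) || !all(tab == 1)) {
    config_error("configuration error: each pair must have exactly one dominant and one subordinate")
  }
  if (any(design$mass_g <= 0)) {
    config_error("configuration error: all masses must be positive")
  }
  if (any(design$chamber_volume_l - design$mass_g / 1000 <= 0)) {
    config_error("configuration error: chamber volume must exceed fish-displaced volume")
  }
  invisible(design)
}

## treatment of each baseline block for one fish, given its block order
block_treatments <- function(treatment_order, n_blocks = 2) {
  first <- if (identical(treatment_order, "social-first")) "social" else "isolation"
  other <- if (first == "social") "isolation" else "social"
  rep(c(first, other), length.out = n_blocks)
}
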