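#' Additive trait architecture
#'
#' Defines one quantitative trait for the simulator: additive allelic effects
#' at a set of QTL drawn from the marker loci, and a narrow-sense
#' heritability controlling the environmental noise added to the genetic
#' value.
#'
#' @param name trait name.
#' @param n_qtl number of QTL (sampled among A/C marker loci).
#' @param h2 narrow-sense heritability in (0, 1].
#' @param effect_sd standard deviation of per-allele additive effects.
#' @param intercept baseline trait value added to every phenotype; keeps
#'   simulated traits on a positive scale (like oil or glucosinolate
#'   content) so relative gains are well defined.
#' @return a list of class `trait_model`.
#' @export
trait_model <- function(name = "index", n_qtl = 20L, h2 = 0.5, effect_sd = 1,
                        intercept = 50) {
  assert_that(n_qtl >= 1, "`n_qtl` must be at least 1")
  assert_that(h2 > 0 && h2 <= 1, "`h2` must be in (0, 1]")
  assert_that(effect_sd > 0, "`effect_sd` must be positive")
  structure(list(name = name, n_qtl = as.integer(n_qtl), h2 = h2,
                 effect_sd = effect_sd, intercept = intercept),
            class = "trait_model")
}

#' Mass recurrent-selection breeding scheme
#'
#' Parameters of the DGMS-mediated mass-selection scheme: sterile (Msms)
#' plants serve as seed parents pollinated at random by fertile (msms)
#' plants; each round the best plants by a weighted phenotype index are
#' retained as parents of the next round. Defaults are desk-scale: 20 DGMS
#' founder lines interplanted with 20 inbred lines per polymorphic
#' subpopulation, 200 plants per round, five rounds.
#'
#' @param n_founders inbred founder lines per polymorphic subpopulation
#'   (Poly-Ar and Poly-Cc).
#' @param n_dgms DGMS (Msms) founder seed-parent lines.
#' @param n_rounds rounds of recurrent selection (>= 0).
#' @param pop_size progeny raised per round.
#' @param sel_fraction fraction of candidates retained by truncation
#'   selection, applied separately to sterile and fertile plants; in (0, 1].
#' @param traits list of [trait_model()] objects.
#' @param trait_weights numeric weights of the selection index (recycled).
#' @param b_seg_rate per-founder, per-B-chromosome probability of carrying a
#'   hemizygous *B. carinata* segment.
#' @return a list of class `breeding_scheme`.
#' @export
breeding_scheme <- function(n_founders = 20L, n_dgms = 20L, n_rounds = 5L,
                            pop_size = 200L, sel_fraction = 0.25,
                            traits = list(trait_model()),
                            trait_weights = 1, b_seg_rate = 0.15) {
  assert_that(n_rounds >= 0, "`n_rounds` must be >= 0")
  assert_that(sel_fraction > 0 && sel_fraction <= 1,
              "`sel_fraction` must be in (0, 1]")
  assert_that(n_founders >= 1 && n_dgms >= 1 && pop_size >= 2,
              "population sizes too small")
  assert_that(length(traits) >= 1 &&
                all(vapply(traits, inherits, TRUE, "trait_model")),
              "`traits` must be a list of trait_model objects")
  assert_that(b_seg_rate >= 0 && b_seg_rate <= 1,
              "`b_seg_rate` must be in [0, 1]")
  w <- rep_len(trait_weights, length(traits))
  structure(list(n_founders = as.integer(n_founders),
                 n_dgms = as.integer(n_dgms),
                 n_rounds = as.integer(n_rounds),
                 pop_size = as.integer(pop_size),
                 sel_fraction = sel_fraction, traits = traits,
                 trait_weights = w, b_seg_rate = b_seg_rate),
            class = "breeding_scheme")
}

# Draw per-allele additive effects for each trait at its QTL. Effects are
# attached to founder allele symbols; novel (mutant) alleles score 0.
draw_trait_effects <- function(panel, traits, ac_markers) {
  lapply(traits, function(tr) {
    qtl <- sample(ac_markers, min(tr$n_qtl, length(ac_markers)))
    eff <- new.env(parent = emptyenv())
    f <- panel$freqs[panel$freqs$marker %in% qtl, ]
    for (al in unique(f$allele)) {
      assign(al, stats::rnorm(1, 0, tr$effect_sd), envir = eff)
    }
    list(qtl = qtl, effects = eff)
  })
}

genetic_values <- function(pop, arch) {
  vapply(seq_len(n_plants(pop)), function(i) {
    g <- 0
    for (m in arch$qtl) {
      for (h in 1:2) {
        a <- pop$hap_allele[[h]][i, m]
        if (exists(a, envir = arch$effects, inherits = FALSE)) {
          g <- g + get(a, envir = arch$effects)
        }
      }
    }
    g
  }, numeric(1))
}

#' Forward-simulate DGMS-mediated mass recurrent selection
#'
#' Runs the breeding scheme: a base population of DGMS seed-parent lines and
#' inbred lines of the Poly-Ar / Poly-Cc subpopulations is intercrossed for
#' `n_rounds` rounds. Each round, sterile (Msms) plants are pollinated by
#' random selected fertile (msms) plants, progeny are phenotyped on a
#' weighted additive index, and truncation selection retains the configured
#' fraction of sterile and fertile candidates as next-round parents.
#' Recombination per chromosome draws a Poisson crossover count with mean
#' equal to the map length in Morgans, positions uniform, no interference.
#'
#' @param founders a [make_founders()] panel.
#' @param scheme a [breeding_scheme()].
#' @param genome the [genome_model()] the panel was built on.
#' @param seed integer seed; identical seeds reproduce the run exactly.
#' @return an object of class `rs_result`: list with `rounds` (list of
#'   `rs_population`, element 1 the base population), `final`, `truth`
#'   ([ancestry_truth()] of the final round), `trait_table` (data.frame
#'   sample, generation, trait, value for every plant of every round),
#'   `scheme` and `genome`.
#' @export
simulate_recurrent_selection <- function(founders, scheme, genome, seed) {
  assert_that(inherits(founders, "founder_panel"),
              "`founders` must be a founder_panel")
  assert_that(inherits(scheme, "breeding_scheme"),
              "`scheme` must be a breeding_scheme")
  assert_that(inherits(genome, "genome_model"), "`genome` must be a genome_model")
  assert_that(identical(sort(founders$markers$marker),
                        sort(genome$markers$marker)),
              "founder panel does not cover the genome model's loci")
  with_seed(seed, {
    idx <- genome_index(genome)
    pop <- make_base_population(founders, genome, scheme)
    arch <- draw_trait_effects(founders, scheme$traits, idx$ac$marker)
    # environmental variance from base-population genetic variance and h2
    base_g <- lapply(arch, function(a) genetic_values(pop, a))
    env_sd <- vapply(seq_along(arch), function(t) {
      vg <- stats::var(base_g[[t]])
      h2 <- scheme$traits[[t]]$h2
      sqrt(max(vg, 1e-12) * (1 - h2) / h2)
    }, numeric(1))
    phenotype <- function(p, g_list = NULL) {
      vals <- lapply(seq_along(arch), function(t) {
        g <- g_list[[t]] %||% genetic_values(p, arch[[t]])
        scheme$traits[[t]]$intercept + g +
          stats::rnorm(n_plants(p), 0, env_sd[t])
      })
      names(vals) <- vapply(scheme$traits, `[[`, "", "name")
      vals
    }
    record <- function(p, ph, gen_label) {
      do.call(rbind, lapply(names(ph), function(tr) {
        data.frame(sample = p$id, generation = gen_label, trait = tr,
                   value = ph[[tr]], stringsAsFactors = FALSE)
      }))
    }
    rounds <- list(pop)
    ph <- phenotype(pop, base_g)
    records <- list(record(pop, ph, "RS0"))
    for (r in seq_len(scheme$n_rounds)) {
      index <- Reduce(`+`, Map(`*`, ph, scheme$trait_weights))
      sterile <- which(is_sterile(pop$dgms))
      fertile <- which(!is_sterile(pop$dgms))
      keep_s <- floor(length(sterile) * scheme$sel_fraction)
      keep_f <- floor(length(fertile) * scheme$sel_fraction)
      if (keep_s < 1 || keep_f < 1) {
        abort(sprintf(
          "selection fraction %.3f leaves no %s parents in round %d",
          scheme$sel_fraction,
          if (keep_s < 1) "sterile (seed)" else "fertile (pollen)", r))
      }
      mothers <- sterile[order(index[sterile], decreasing = TRUE)][seq_len(keep_s)]
      fathers <- fertile[order(index[fertile], decreasing = TRUE)][seq_len(keep_f)]
      n <- scheme$pop_size
      mAC <- ncol(pop$hap_allele[[1]]); mB <- ncol(pop$b_pres)
      marker_names <- colnames(pop$hap_allele[[1]])
      hap_allele <- list(matrix(NA_character_, n, mAC,
                                dimnames = list(NULL, marker_names)),
                         matrix(NA_character_, n, mAC,
                                dimnames = list(NULL, marker_names)))
      hap_origin <- list(matrix(NA_character_, n, mAC),
                         matrix(NA_character_, n, mAC))
      b_pres <- matrix(FALSE, n, mB, dimnames = list(NULL, colnames(pop$b_pres)))
      b_allele <- matrix(NA_character_, n, mB,
                         dimnames = list(NULL, colnames(pop$b_pres)))
      dgms <- character(n)
      mom_pick <- sample(mothers, n, replace = TRUE)
      dad_pick <- sample(fathers, n, replace = TRUE)
      for (j in seq_len(n)) {
        gm <- make_gamete(pop, mom_pick[j], idx)
        gf <- make_gamete(pop, dad_pick[j], idx)
        hap_allele[[1]][j, ] <- gm$allele; hap_origin[[1]][j, ] <- gm$origin
        hap_allele[[2]][j, ] <- gf$allele; hap_origin[[2]][j, ] <- gf$origin
        if (mB) {
          b_pres[j, ] <- gm$b_pres | gf$b_pres
          b_allele[j, ] <- ifelse(gm$b_pres, gm$b_allele, gf$b_allele)
        }
        dgms[j] <- paste0(gm$dgms, gf$dgms)
      }
      pop <- new_population(hap_allele, hap_origin, b_pres, b_allele, dgms,
                            id = sprintf("RS%d_%04d", r, seq_len(n)),
                            subpop = rep("RS", n), generation = r,
                            genome = genome, novel_rate = founders$novel_rate)
      rounds[[r + 1L]] <- pop
      ph <- phenotype(pop)
      records[[r + 1L]] <- record(pop, ph, sprintf("RS%d", r))
    }
    trait_table <- do.call(rbind, records)
    rownames(trait_table) <- NULL
    structure(list(rounds = rounds, final = pop, truth = ancestry_truth(pop),
                   trait_table = trait_table, scheme = scheme,
                   genome = genome),
              class = "rs_result")
  })
}

#' @export
print.rs_result <- function(x, ...) {
  cat("rs_result:", length(x$rounds) - 1L, "rounds of recurrent selection,",
      n_plants(x$final), "plants in the final population\n")
  invisible(x)
}
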