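# Recurrent-selection response statistics: relative genetic gain between
# rounds and per-generation trait summaries and comparisons.

#' Relative genetic gain between two selection rounds
#'
#' Delta-G = (mu_n - mu_i) / mu_i, the relative change in a trait's
#' population mean from round i to round n.
#'
#' @param mu_i mean of the earlier round (nonzero).
#' @param mu_n mean of the later round.
#' @param percent return percent instead of a signed fraction.
#' @return signed fraction (or percent); vectorized over its arguments.
#' @examples
#' delta_g(60.9, 36.2)          # glucosinolate-style decline
#' delta_g(10, 11, percent = TRUE)
#' @export
delta_g <- function(mu_i, mu_n, percent = FALSE) {
  assert_that(is.numeric(mu_i) && is.numeric(mu_n),
              "means must be numeric")
  if (any(mu_i == 0)) {
    abort("delta_g is undefined for a zero baseline mean")
  }
  g <- (mu_n - mu_i) / mu_i
  if (percent) 100 * g else g
}

validate_trait_table <- function(trait_table) {
  req <- c("sample", "generation", "trait", "value")
  assert_that(is.data.frame(trait_table) && all(req %in% names(trait_table)),
              "trait table needs columns sample, generation, trait, value")
  assert_that(is.numeric(trait_table$value) && all(is.finite(trait_table$value)),
              "trait values must be finite numbers")
  invisible(trait_table)
}

generation_levels <- function(generation) {
  if (is.factor(generation)) levels(generation) else sort(unique(generation))
}

#' Per-generation trait summaries and pairwise gains
#'
#' Computes mean, min, max and n per generation and trait, plus for each
#' trait the matrix of [delta_g()] gains between all ordered generation
#' pairs (rows = from, columns = to). Generations without records are
#' dropped with a warning.
#'
#' @param trait_table data.frame with columns sample, generation, trait,
#'   value; `generation` may be a factor to fix the round order.
#' @return list with `stats` (data.frame generation, trait, n, mean, min,
#'   max) and `delta_g` (named list of gain matrices per trait).
#' @export
generation_summary <- function(trait_table) {
  validate_trait_table(trait_table)
  gens <- generation_levels(trait_table$generation)
  present <- gens %in% trait_table$generation
  if (any(!present)) {
    warning("generations without records omitted: ",
            paste(gens[!present], collapse = ", "))
    gens <- gens[present]
  }
  traits <- sort(unique(trait_table$trait))
  stats_rows <- list()
  gains <- list()
  for (tr in traits) {
    sub <- trait_table[trait_table$trait == tr, , drop = FALSE]
    mu <- vapply(gens, function(gn) mean(sub$value[sub$generation == gn]),
                 numeric(1))
    for (gn in gens) {
      v <- sub$value[sub$generation == gn]
      if (!length(v)) next
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        generation = gn, trait = tr, n = length(v), mean = mean(v),
        min = min(v), max = max(v), stringsAsFactors = FALSE)
    }
    ok <- !is.na(mu) & mu != 0
    gm <- matrix(NA_real_, length(gens), length(gens),
                 dimnames = list(from = gens, to = gens))
    for (i in which(ok)) gm[i, ] <- delta_g(mu[i], mu)
    gains[[tr]] <- gm
  }
  list(stats = do.call(rbind, stats_rows), delta_g = gains)
}

#' Test trait differences across generations
#'
#' One-way ANOVA F test of a trait over generations by default, with a
#' rank-based (Kruskal-Wallis) alternative; degenerate within-generation
#' variance triggers the rank-based fallback with a message. The p-value is
#' reported as is; no significance decision is taken here.
#'
#' @param trait_table data.frame with columns sample, generation, trait,
#'   value.
#' @param trait trait name to test.
#' @param method "anova" (default) or "kruskal".
#' @return list: statistic, p_value, df, method, n_per_generation.
#' @export
generation_difference_test <- function(trait_table, trait,
                                       method = c("anova", "kruskal")) {
  validate_trait_table(trait_table)
  method <- match.arg(method)
  sub <- trait_table[trait_table$trait == trait, , drop = FALSE]
  assert_that(nrow(sub) > 0, sprintf("no records for trait '%s'", trait))
  sub$generation <- factor(sub$generation)
  counts <- table(sub$generation)
  assert_that(length(counts) >= 2 && all(counts >= 2),
              "need at least two generations with at least two records each")
  within_var <- tapply(sub$value, sub$generation, stats::var)
  if (method == "anova" && all(within_var < .Machine$double.eps)) {
    message("degenerate within-generation variance; falling back to the rank-based test")
    method <- "kruskal"
  }
  if (method == "anova") {
    fit <- stats::aov(value ~ generation, data = sub)
    tab <- summary(fit)[[1]]
    list(statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
         df = tab[["Df"]], method = "one-way ANOVA",
         n_per_generation = as.vector(counts))
  } else {
    kt <- stats::kruskal.test(value ~ generation, data = sub)
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         df = unname(kt$parameter), method = "Kruskal-Wallis",
         n_per_generation = as.vector(counts))
  }
}
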