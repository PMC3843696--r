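## Forward-time simulation of mixed cultivated stands of a predominantly
## self-pollinating annual. Lines are effectively haploid multilocus
## genotypes (selfing keeps them homozygous); an outcross event replaces
## the succession of the participating line(s) by a free-recombination
## mosaic of the two parents. Founder populations are internally uniform
## and fixed for population-diagnostic alleles at every locus, so a line
## retains a founder genotype exactly when all its loci trace to one
## founder.

#' Configuration of the population-mixing simulation
#'
#' @param k number of founder populations (default 2).
#' @param proportions founder mixture fractions, summing to 1 (default
#'   equal).
#' @param N stand size in lines (default 1000).
#' @param L number of population-diagnostic loci (default 20).
#' @param c cross-pollination frequency per generation: the expected number
#'   of outcross events is `c * N`. Under `"maternal-only"` an event
#'   re-derives one line (a fraction c of lines affected, survival envelope
#'   (1-c)^t); under `"symmetric-pair"` (default) both participants'
#'   successions are recombinant (fraction ~2c affected).
#' @param scheme `"symmetric-pair"` or `"maternal-only"`.
#' @param generations number of generations (default 200).
#' @param replicates Monte Carlo replicates (default 20).
#' @param seed RNG seed.
#' @return a `sim_config` object.
#' @export
sim_config <- function(k = 2L, proportions = rep(1 / k, k), N = 1000L,
                       L = 20L, c = 0.01,
                       scheme = c("symmetric-pair", "maternal-only"),
                       generations = 200L, replicates = 20L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (length(proportions) != k || abs(sum(proportions) - 1) > 1e-8)
    stop("config error: proportions must be length k and sum to 1")
  if (c < 0 || c > 1) stop("config error: c must lie in [0, 1]")
  if (N * min(proportions) < 1)
    stop("config error: every founder population needs at least one line")
  structure(list(k = as.integer(k), proportions = proportions,
                 N = as.integer(N), L = as.integer(L), c = c,
                 scheme = scheme, generations = as.integer(generations),
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate founder-genotype loss under rare outcrossing
#'
#' Each generation every line is succeeded by selfed seed (genotype
#' copied), except for outcross events whose number is Binomial(N, c):
#' an event picks parents and replaces the succession of one
#' (maternal-only) or both (symmetric-pair) participants with independent
#' free-recombination mosaics (each locus inherited from either parent
#' with probability 1/2). No selection, constant N.
#'
#' @param cfg a [sim_config()].
#' @return object of class `mixing_trajectory`: list with `freq`
#'   ((generations+1) x replicates matrix of founder-genotype frequencies),
#'   `mean_freq`, `n_genotypes` (mean distinct genotype count per
#'   generation), `allele_freq` (per-replicate share of founder-1 alleles,
#'   averaged over loci: conserved in expectation since there is no
#'   selection or mutation), `config`.
#' @export
simulate_mixing <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  G <- cfg$generations; N <- cfg$N; L <- cfg$L
  freq <- matrix(NA_real_, G + 1L, cfg$replicates)
  ngen <- matrix(NA_real_, G + 1L, cfg$replicates)
  afreq <- matrix(NA_real_, G + 1L, cfg$replicates)
  set.seed(cfg$seed)
  sizes <- floor(cfg$proportions * N)
  sizes[1L] <- N - sum(sizes[-1L])
  for (rep_ in seq_len(cfg$replicates)) {
    geno <- matrix(rep(rep.int(seq_len(cfg$k), sizes), L), N, L)
    freq[1L, rep_] <- 1
    ngen[1L, rep_] <- cfg$k
    afreq[1L, rep_] <- mean(geno == 1L)
    for (g in seq_len(G)) {
      n_ev <- stats::rbinom(1L, N, cfg$c)
      if (n_ev > 0L) {
        nxt <- geno
        for (e in seq_len(n_ev)) {
          if (cfg$scheme == "maternal-only") {
            i <- sample.int(N, 1L)
            j <- sample.int(N - 1L, 1L); if (j >= i) j <- j + 1L
            pick <- stats::runif(L) < 0.5
            nxt[i, ] <- ifelse(pick, geno[i, ], geno[j, ])
          } else {
            ij <- sample.int(N, 2L)
            for (x in 1:2) {
              pick <- stats::runif(L) < 0.5
              nxt[ij[x], ] <- ifelse(pick, geno[ij[1L], ], geno[ij[2L], ])
            }
          }
        }
        geno <- nxt
      }
      fr <- rowSums(geno == geno[, 1L]) == L
      freq[g + 1L, rep_] <- mean(fr)
      ngen[g + 1L, rep_] <- nrow(unique(geno))
      afreq[g + 1L, rep_] <- mean(geno == 1L)
    }
  }
  structure(list(freq = freq, mean_freq = rowMeans(freq),
                 n_genotypes = rowMeans(ngen), allele_freq = afreq,
                 config = cfg),
            class = "mixing_trajectory")
}

#' @export
print.mixing_trajectory <- function(x, ...) {
  G <- x$config$generations
  cat(sprintf(
    "mixing_trajectory: %s scheme, c = %g, %d generations, %d replicates\n",
    x$config$scheme, x$config$c, G, x$config$replicates))
  cat(sprintf("  founder-genotype frequency at generation %d: %.3f (mean)\n",
              G, x$mean_freq[G + 1L]))
  invisible(x)
}

#' @export
plot.mixing_trajectory <- function(x, ...) {
  gens <- seq_len(nrow(x$freq)) - 1L
  graphics::matplot(gens, x$freq, type = "l", lty = 1, col = "grey70",
                    xlab = "generation", ylab = "founder-genotype frequency",
                    ylim = c(0, 1), ...)
  graphics::lines(gens, x$mean_freq, lwd = 2)
  invisible(x)
}

#' Compare mixing scenarios along one axis
#'
#' Runs each configuration and reports the first generation at which the
#' mean founder-genotype frequency drops below `threshold`.
#'
#' @param cfgs list of [sim_config()] objects.
#' @param threshold frequency threshold (default 0.10).
#' @return data.frame with one row per config: `k`, `c`, `scheme`,
#'   `threshold_generation` (NA when never reached), `final_freq`.
#' @export
compare_scenarios <- function(cfgs, threshold = 0.10) {
  rows <- lapply(cfgs, function(cfg) {
    tr <- simulate_mixing(cfg)
    hit <- which(tr$mean_freq < threshold)
    data.frame(k = cfg$k, c = cfg$c, scheme = cfg$scheme,
               threshold_generation = if (length(hit)) hit[1L] - 1L else NA,
               final_freq = tr$mean_freq[length(tr$mean_freq)])
  })
  do.call(rbind, rows)
}
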