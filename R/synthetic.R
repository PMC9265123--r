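#' Describe one synthetic cancer class
#'
#' A class is defined by an interchromosomal translocation signature (a
#' probability distribution over ordered chromosome pairs), the expected
#' fraction of intrachromosomal events, and the distribution of typed
#' mutation kinds among those intrachromosomal events.
#'
#' @param label Class label.
#' @param n_samples Number of samples to generate for the class.
#' @param signature Data frame with columns `from`, `to`, `prob`:
#'   probability mass over ordered interchromosomal pairs (normalized
#'   internally).
#' @param intra_rate Expected fraction of intrachromosomal aberrations, in
#'   \[0, 1\]. Defaults to 0.75: in real catalogues intrachromosomal events
#'   outnumber interchromosomal roughly three to one.
#' @param intra_type_distribution Named probability vector over the six
#'   typed mutation kinds; default uniform.
#' @return List describing the class, for [synthetic_config()].
#' @export
synthetic_class <- function(label, n_samples, signature, intra_rate = 0.75,
                            intra_type_distribution = NULL) {
  stopifnot(n_samples >= 1, intra_rate >= 0, intra_rate <= 1)
  stopifnot(all(c("from", "to", "prob") %in% names(signature)))
  if (any(signature$from == signature$to)) {
    stop("signature pairs must be interchromosomal (from != to)")
  }
  signature$prob <- signature$prob / sum(signature$prob)
  typed <- setdiff(mutation_types(), "unknown")
  if (is.null(intra_type_distribution)) {
    intra_type_distribution <- stats::setNames(rep(1 / 6, 6), typed)
  }
  stopifnot(setequal(names(intra_type_distribution), typed))
  intra_type_distribution <- intra_type_distribution /
    sum(intra_type_distribution)
  list(label = label, n_samples = n_samples, signature = signature,
       intra_rate = intra_rate,
       intra_type_distribution = intra_type_distribution)
}

#' Configuration for the synthetic breakpoint-cohort generator
#'
#' @param classes List of class descriptions from [synthetic_class()].
#' @param aberrations_per_sample List with `mean` and `dispersion`: the
#'   per-sample aberration count is drawn from a negative binomial with
#'   that mean and size (dispersion), floored at 1. The default spans
#'   sparse to dense graphs so the connectivity filter genuinely
#'   partitions a cohort.
#' @param background_rate Probability that an interchromosomal event draws
#'   a uniform random ordered pair instead of the class signature (noise).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(classes,
                             aberrations_per_sample = list(mean = 75,
                                                           dispersion = 3),
                             background_rate = 0.1, seed = 0L) {
  stopifnot(length(classes) >= 1,
            background_rate >= 0, background_rate <= 1)
  structure(list(classes = classes,
                 aberrations_per_sample = aberrations_per_sample,
                 background_rate = background_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic COSMIC-like breakpoint cohort
#'
#' For each sample: draw its aberration count, then for each aberration
#' decide intra- versus interchromosomal by the class `intra_rate`.
#' Interchromosomal events draw an ordered chromosome pair from the mixture
#' `(1 - background_rate) * signature + background_rate * uniform` and are
#' typed `"unknown"` (the COSMIC convention); intrachromosomal events draw
#' one chromosome uniformly and a typed mutation kind from the class
#' distribution. Breakpoint coordinates are uniform placeholders. The
#' output uses the same record schema as [read_breakpoints()].
#'
#' @param config A [synthetic_config()].
#' @return Record data frame (`sample_id`, `cancer_type`, `chrom_from`,
#'   `chrom_to`, `pos_from`, `pos_to`, `mutation_type`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  pieces <- list()
  for (cl in config$classes) {
    mu <- config$aberrations_per_sample$mean
    size <- config$aberrations_per_sample$dispersion
    counts <- pmax(1L, stats::rnbinom(cl$n_samples, mu = mu, size = size))
    n_ab <- sum(counts)
    sample_ids <- rep(sprintf("%s_%04d", cl$label, seq_len(cl$n_samples)),
                      counts)
    is_intra <- stats::runif(n_ab) < cl$intra_rate
    cf <- integer(n_ab)
    ct <- integer(n_ab)
    mt <- rep("unknown", n_ab)
    # intrachromosomal: one uniform chromosome, typed mutation
    n_i <- sum(is_intra)
    if (n_i > 0) {
      chrom <- sample.int(N_CHROM, n_i, replace = TRUE)
      cf[is_intra] <- chrom
      ct[is_intra] <- chrom
      mt[is_intra] <- sample(names(cl$intra_type_distribution), n_i,
                             replace = TRUE,
                             prob = cl$intra_type_distribution)
    }
    # interchromosomal: signature vs uniform background
    n_e <- n_ab - n_i
    if (n_e > 0) {
      bg <- stats::runif(n_e) < config$background_rate
      n_sig <- sum(!bg)
      if (n_sig > 0) {
        k <- sample.int(nrow(cl$signature), n_sig, replace = TRUE,
                        prob = cl$signature$prob)
        idx <- which(!is_intra)[!bg]
        cf[idx] <- cl$signature$from[k]
        ct[idx] <- cl$signature$to[k]
      }
      n_bg <- sum(bg)
      if (n_bg > 0) {
        a <- sample.int(N_CHROM, n_bg, replace = TRUE)
        shift <- sample.int(N_CHROM - 1L, n_bg, replace = TRUE)
        b <- ((a - 1L + shift) %% N_CHROM) + 1L   # uniform over pairs b != a
        idx <- which(!is_intra)[bg]
        cf[idx] <- a
        ct[idx] <- b
      }
    }
    pieces[[cl$label]] <- data.frame(
      sample_id = sample_ids,
      cancer_type = cl$label,
      chrom_from = cf,
      chrom_to = ct,
      pos_from = as.numeric(sample.int(2e8L, n_ab, replace = TRUE)),
      pos_to = as.numeric(sample.int(2e8L, n_ab, replace = TRUE)),
      mutation_type = mt,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' A linearly separable three-class synthetic cohort
#'
#' Three cancer classes with disjoint dominant interchromosomal signatures
#' (breast on 1-2 and 3-4, pancreatic on 5-6 and 7-8, prostate on 9-10 and
#' 11-12), a moderate intrachromosomal background that carries no class
#' information, and an aberration-count distribution wide enough that the
#' default connectivity filter keeps the majority of samples but not all.
#'
#' @param n_per_class Samples per class, at least 20.
#' @param seed Integer seed.
#' @return Record data frame as from [generate_cohort()].
#' @export
make_separable_cohort <- function(n_per_class = 200L, seed = 0L) {
  stopifnot(n_per_class >= 20)
  sig <- function(pairs) {
    data.frame(from = pairs[c(TRUE, FALSE)], to = pairs[c(FALSE, TRUE)],
               prob = rep(0.5, 2))
  }
  config <- synthetic_config(
    classes = list(
      synthetic_class("breast",     n_per_class, sig(c(1L, 2L, 3L, 4L)),
                      intra_rate = 0.3),
      synthetic_class("pancreatic", n_per_class, sig(c(5L, 6L, 7L, 8L)),
                      intra_rate = 0.3),
      synthetic_class("prostate",   n_per_class, sig(c(9L, 10L, 11L, 12L)),
                      intra_rate = 0.3)
    ),
    aberrations_per_sample = list(mean = 100, dispersion = 3),
    background_rate = 0.25,
    seed = seed
  )
  generate_cohort(config)
}
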