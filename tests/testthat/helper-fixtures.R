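# Shared fixtures and independent oracles.

fixture_life_tables <- function(seed = 1) {
  generate_life_tables(synthetic_config(seed = seed))
}

fixture_rates <- function(seed = 1) {
  life_table_to_rates(fixture_life_tables(seed))
}

# Calibrated default setup (q to 10% emergence, gamma to K = 500 at 28 C),
# computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())
fixture_calibrated <- function() {
  if (is.null(.fixture_cache$cal)) {
    rl <- fixture_rates()
    ref <- reference_rates(rl, 28)
    q <- calibrate_field_adjustment(ref, target_emergence = 0.10)
    rates_q <- lapply(rl, add_field_mortality, q = q)
    gamma <- calibrate_density_dependence(rates_q, K = 500)
    .fixture_cache$cal <- list(
      rates = rl, ref = ref, q = q, rates_q = rates_q,
      ref_q = reference_rates(rates_q, 28), gamma = gamma, K = 500
    )
  }
  .fixture_cache$cal
}

# Brute-force daily cohort simulation of the stay/advance/die chain:
# each day the individuals in each immature stage are split multinomially
# into (advance, die, stay). Returns the realized egg-to-adult fraction.
cohort_emergence <- function(rates, n = 1e5) {
  counts <- c(n, 0, 0)
  emerged <- 0
  while (sum(counts) > 0) {
    nxt <- c(0, 0, 0)
    for (i in 1:3) {
      if (counts[i] == 0) next
      draw <- stats::rmultinom(1, counts[i],
                               c(rates$r[[i]], rates$d[[i]], rates$s[[i]]))
      if (i < 3) nxt[i + 1] <- nxt[i + 1] + draw[1] else emerged <- emerged + draw[1]
      nxt[i] <- nxt[i] + draw[3]
    }
    counts <- nxt
  }
  emerged / n
}

# Scalar fixed-point oracle for the constant-temperature equilibrium: the
# immature stage abundances are eliminated analytically, leaving one equation
# in the adult density solved by root finding.
equilibrium_adults_oracle <- function(rates, gamma) {
  s <- rates$s
  r <- rates$r
  fec <- rates$fecundity
  d_adult <- rates$d_adult
  f <- function(A) {
    E <- fec * A / (1 - s[["egg"]])
    N <- r[["egg"]] * E / (1 - s[["nymph"]])
    P <- r[["nymph"]] * N / (1 - s[["pupa"]])
    A_next <- r[["pupa"]] * P + (1 - d_adult) * A
    A_next - gamma * A_next^2 - A
  }
  stats::uniroot(f, c(1, 1e7), tol = 1e-10)$root
}

# Independent exact-match oracle built on Biostrings::matchPattern.
oracle_screen <- function(dsrnas, references, k = 21L, both_strands = TRUE) {
  rows <- list()
  for (did in names(dsrnas)) {
    km <- suppressWarnings(kmerize(dsrnas[[did]], k = k))
    kmers <- unique(km$kmer[km$matchable])
    for (rid in names(references)) {
      subject <- Biostrings::DNAString(references[[rid]])
      for (kmer in kmers) {
        st <- Biostrings::start(Biostrings::matchPattern(kmer, subject))
        if (length(st)) {
          rows[[length(rows) + 1L]] <- data.frame(
            dsrna_id = did, ref_id = rid, kmer = kmer,
            position = st, strand = "+"
          )
        }
        if (both_strands) {
          st <- Biostrings::start(
            Biostrings::matchPattern(reverse_complement(kmer), subject)
          )
          if (length(st)) {
            rows[[length(rows) + 1L]] <- data.frame(
              dsrna_id = did, ref_id = rid, kmer = kmer,
              position = st, strand = "-"
            )
          }
        }
      }
    }
  }
  hits <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(dsrna_id = character(0), ref_id = character(0),
               kmer = character(0), position = integer(0),
               strand = character(0))
  }
  hits <- hits[order(hits$dsrna_id, hits$ref_id, hits$position, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Random-but-valid daily rates for property tests.
random_daily_rates <- function() {
  r <- stats::runif(3, 0.05, 0.5)
  d <- stats::runif(3, 0.01, pmin(0.45, 1 - r))
  daily_rates(r, d, d_adult = stats::runif(1, 0.02, 0.3),
              fecundity = stats::runif(1, 0, 10), temperature = 28)
}
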