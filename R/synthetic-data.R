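#' Configuration for synthetic model inputs
#'
#' Bundles the knobs used by the synthetic-data generators: the RNG seed, the
#' length and shape of the daily temperature series, and the anchor
#' temperatures at which life tables are tabulated. Defaults describe a
#' tropical, near-constant climate (Kampala-like): mean 23 degrees C, seasonal
#' amplitude 4 degrees C, day-to-day noise sd 1 degree C, inside the
#' 16--32 degrees C anchor range.
#'
#' @param seed Integer RNG seed; identical configurations yield byte-identical
#'   artifacts.
#' @param n_days Number of daily temperature values to generate.
#' @param temp_mean Mean of the seasonal temperature cycle, degrees C.
#' @param temp_amplitude Amplitude of the seasonal sinusoid, degrees C.
#' @param temp_noise_sd Standard deviation of daily Gaussian noise, degrees C.
#' @param anchor_temps Sorted vector (>= 2 entries) of anchor temperatures,
#'   degrees C, at which life tables are produced and transition matrices are
#'   anchored.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_days = 365L,
                             temp_mean = 23,
                             temp_amplitude = 4,
                             temp_noise_sd = 1,
                             anchor_temps = c(16, 20, 24, 28, 32)) {
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1) {
    stop("`n_days` must be a positive integer", call. = FALSE)
  }
  if (length(anchor_temps) < 2L) {
    stop("at least two anchor temperatures are required", call. = FALSE)
  }
  if (is.unsorted(anchor_temps, strictly = TRUE)) {
    stop("`anchor_temps` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_days = as.integer(n_days),
      temp_mean = temp_mean,
      temp_amplitude = temp_amplitude,
      temp_noise_sd = temp_noise_sd,
      anchor_temps = as.numeric(anchor_temps)
    ),
    class = "synthetic_config"
  )
}

# Baseline vital rates at the 28 C optimum. Durations in days, survivals are
# per-stage fractions (adult survival is daily), fecundity in eggs/adult/day.
# Chosen so that egg-to-adult development sums to 20 days at 28 C.
.lt_base <- list(
  m_egg = 6, T1 = 3, T2 = 3, T3 = 2, T4 = 2, m_pupa = 4,
  s_egg = 0.90, s_n = 0.95, s_pupa = 0.90, s_adult = 0.95,
  fecundity = 5
)

#' Generate synthetic whitefly life tables at the anchor temperatures
#'
#' Emits one life table per anchor temperature with the qualitative structure
#' laboratory studies report for *Bemisia tabaci*: development is fastest and
#' fecundity highest near 28 degrees C and both degrade smoothly (quadratically)
#' toward the extremes; survivals decline mildly away from the optimum. The
#' curves are deterministic functions of temperature, so a given configuration
#' always produces byte-identical tables. At 28 degrees C the median
#' egg-to-adult development time is 20 days (egg 6 + nymph 10 + pupa 4).
#'
#' Columns: `temperature`; median development times `m_egg`, `T1`--`T4`
#' (the four nymphal instars), `m_pupa` (days); stage survival fractions
#' `s_egg`, `s_n1`--`s_n4`, `s_pupa`; daily adult survival `s_adult`; and
#' `fecundity` (eggs per adult per day).
#'
#' @param config A [synthetic_config()].
#' @return A data frame, one row per anchor temperature.
#' @export
generate_life_tables <- function(config = synthetic_config()) {
  tt <- config$anchor_temps
  b <- .lt_base
  dev_f <- 1 + 0.006 * (tt - 28)^2        # durations stretch away from 28 C
  surv_f <- pmax(0.05, 1 - 0.0008 * (tt - 28)^2)
  fec_f <- pmax(0, 1 - 0.005 * (tt - 28)^2)
  data.frame(
    temperature = tt,
    m_egg = pmax(1, b$m_egg * dev_f),
    T1 = pmax(1, b$T1 * dev_f),
    T2 = pmax(1, b$T2 * dev_f),
    T3 = pmax(1, b$T3 * dev_f),
    T4 = pmax(1, b$T4 * dev_f),
    m_pupa = pmax(1, b$m_pupa * dev_f),
    s_egg = pmin(1, b$s_egg * surv_f),
    s_n1 = pmin(1, b$s_n * surv_f),
    s_n2 = pmin(1, b$s_n * surv_f),
    s_n3 = pmin(1, b$s_n * surv_f),
    s_n4 = pmin(1, b$s_n * surv_f),
    s_pupa = pmin(1, b$s_pupa * surv_f),
    s_adult = pmin(1, b$s_adult * surv_f),
    fecundity = b$fecundity * fec_f
  )
}

#' Generate a daily mean-temperature series
#'
#' A sinusoidal seasonal cycle (period 365 days) plus Gaussian daily noise,
#' clamped to the anchor-temperature range so interpolation between anchor
#' matrices is always defined without extrapolation.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `day` (1-based index) and `temperature`
#'   (degrees C).
#' @export
generate_temperature_series <- function(config = synthetic_config()) {
  set.seed(config$seed)
  d <- seq_len(config$n_days)
  temp <- config$temp_mean +
    config$temp_amplitude * sin(2 * pi * (d - 1) / 365) +
    stats::rnorm(config$n_days, 0, config$temp_noise_sd)
  rng <- range(config$anchor_temps)
  data.frame(day = d, temperature = pmin(pmax(temp, rng[1]), rng[2]))
}

.random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a dsRNA / reference sequence fixture panel
#'
#' Produces random A/C/G/T dsRNA candidates and reference sequences, optionally
#' planting exact 21-mers copied from a dsRNA into a reference at a stated
#' position, on either strand (reverse-strand plantings are inserted as the
#' reverse complement of the dsRNA 21-mer). Intended as a controlled fixture
#' for the off-target screen: every planted entry is a known true positive.
#'
#' @param seed Integer RNG seed.
#' @param n_dsrna,dsrna_length Number and length (nt) of dsRNA candidates.
#' @param n_refs,ref_length Number and length (nt) of reference sequences.
#' @param planted List of plantings, each a list with elements `dsrna` and
#'   `ref` (sequence ids), `strand` (`"+"` or `"-"`), `position` (1-based start
#'   in the reference) and optionally `kmer_start` (1-based start of the 21-mer
#'   within the dsRNA, default 1).
#' @param ref_alphabet Alphabet for reference sequences (default A/C/G/T);
#'   restricting it (e.g. to `"A"`) yields references that cannot share 21-mers
#'   with a generic dsRNA.
#' @return List with named character vectors `dsrna` and `references`.
#' @export
generate_sequence_panel <- function(seed = 1L,
                                    n_dsrna = 2L,
                                    dsrna_length = 200L,
                                    n_refs = 2L,
                                    ref_length = 1000L,
                                    planted = list(),
                                    ref_alphabet = c("A", "C", "G", "T")) {
  k <- 21L
  set.seed(seed)
  dsrna <- stats::setNames(
    vapply(seq_len(n_dsrna), function(i) .random_seq(dsrna_length), character(1)),
    paste0("dsRNA_", seq_len(n_dsrna))
  )
  refs <- stats::setNames(
    vapply(seq_len(n_refs), function(i) .random_seq(ref_length, ref_alphabet), character(1)),
    paste0("ref_", seq_len(n_refs))
  )
  for (p in planted) {
    if (!p$dsrna %in% names(dsrna)) stop("unknown dsRNA id: ", p$dsrna, call. = FALSE)
    if (!p$ref %in% names(refs)) stop("unknown reference id: ", p$ref, call. = FALSE)
    if (nchar(dsrna[[p$dsrna]]) < k) {
      stop("cannot plant a 21-mer from a dsRNA shorter than 21 nt", call. = FALSE)
    }
    ks <- if (is.null(p$kmer_start)) 1L else as.integer(p$kmer_start)
    if (ks < 1L || ks + k - 1L > nchar(dsrna[[p$dsrna]])) {
      stop("k-mer start outside the dsRNA sequence", call. = FALSE)
    }
    if (p$position < 1L || p$position + k - 1L > nchar(refs[[p$ref]])) {
      stop("planted position does not fit within the reference", call. = FALSE)
    }
    kmer <- substr(dsrna[[p$dsrna]], ks, ks + k - 1L)
    if (identical(p$strand, "-")) kmer <- reverse_complement(kmer)
    substr(refs[[p$ref]], p$position, p$position + k - 1L) <- kmer
  }
  list(dsrna = dsrna, references = refs)
}

#' Read and write plain FASTA
#'
#' Thin wrappers over Biostrings for the fixture panels: sequences are handled
#' as named character vectors of uppercase A/C/G/T/N.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}
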