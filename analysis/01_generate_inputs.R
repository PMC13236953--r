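#!/usr/bin/env Rscript
# Generate every input the analysis needs: life tables at the five anchor
# temperatures, a two-year Kampala-like daily temperature series, and a
# dsRNA / reference FASTA fixture panel with known planted 21-mers.

suppressMessages(library(whiteflysim))

out_dir <- "results/inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 1, n_days = 730)

life_tables <- generate_life_tables(cfg)
write.csv(life_tables, file.path(out_dir, "life_tables.csv"), row.names = FALSE)
message("life tables: ", nrow(life_tables), " anchor temperatures; ",
        "egg-to-adult development at 28 C = ",
        with(life_tables[life_tables$temperature == 28, ],
             m_egg + T1 + T2 + T3 + T4 + m_pupa), " days")

temps <- generate_temperature_series(cfg)
write.csv(temps, file.path(out_dir, "temperature_series.csv"), row.names = FALSE)
message(sprintf("temperature series: %d days, mean %.1f C, range [%.1f, %.1f] C",
                nrow(temps), mean(temps$temperature),
                min(temps$temperature), max(temps$temperature)))

panel <- generate_sequence_panel(
  seed = 1, n_dsrna = 3, dsrna_length = 300, n_refs = 4, ref_length = 5000,
  planted = list(
    list(dsrna = "dsRNA_1", ref = "ref_2", strand = "+", position = 1200),
    list(dsrna = "dsRNA_3", ref = "ref_4", strand = "-", position = 3100)
  )
)
write_fasta(panel$dsrna, file.path(out_dir, "dsrna_candidates.fasta"))
write_fasta(panel$references, file.path(out_dir, "reference_panel.fasta"))
message("sequence panel: ", length(panel$dsrna), " dsRNA candidates, ",
        length(panel$references), " references (two 21-mers planted)")
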