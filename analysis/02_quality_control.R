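# Read-level quality control and negative-control decontamination.
# Raw amplicon reads are simulated for every sequenced sample (barcode +
# primer + 311-bp template) with mild corruption, filtered by the three
# criteria (perfect barcode/primer, >= 300 bp, <= 2 ambiguous bases), and
# the OTU table is stripped of every OTU detected in the blank control.

source("analysis/_common.R")

study <- load_study()
tab <- unclass(study$table)

primer <- "AGAGTTTGATCATGGCTCAG"
bases <- c("A", "C", "G", "T")
# sample index in base 4 over ten positions: unique by construction
barcodes <- vapply(seq_len(nrow(tab)), function(i)
  paste(bases[1 + (i %/% 4^(9:0)) %% 4], collapse = ""), character(1))
stopifnot(!anyDuplicated(barcodes))

reads <- unlist(lapply(seq_len(nrow(tab)), function(i)
  simulate_reads(tab[i, ], barcodes[i], primer,
                 error_profile = c(barcode = 0.03, truncation = 0.04,
                                   ambiguity = 0.02),
                 seed = sub_seed(SEED, paste0("reads", i)))))
flt <- filter_reads(reads, setNames(rownames(tab), barcodes), primer)
print(flt$report)
write_tsv(data.frame(unclass(flt$report)),
          file.path(RESULTS, "filter_report.tsv"))

dec <- decontaminated(study)
cat(sprintf("Decontamination removed %d OTUs found in the blank control\n",
            length(dec$removed_otus)))
write_otu_table(dec$table, file.path(STUDY_DIR, "otu_table_filtered.tsv"))
writeLines(dec$removed_otus, file.path(RESULTS, "removed_otus.txt"))
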