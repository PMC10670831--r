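# Shared fixture builders: everything generated in code, nothing on disk.

toy_table <- function(counts = rbind(c(5, 0), c(1, 2), c(0, 7)),
                      site = "caecum") {
  rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  genus_count_table(counts, site = site)
}

toy_metadata <- function(sample_ids, treatment = NULL, site = "caecum") {
  n <- length(sample_ids)
  if (is.null(treatment)) treatment <- rep(c("stress", "control"), length.out = n)
  data.frame(sample_id = sample_ids,
             animal_id = paste0("A", seq_len(n)),
             treatment = treatment,
             litter = paste0("L", rep(seq_len(max(2, ceiling(n / 4))),
                                      length.out = n)),
             pen = paste0("P", rep(1:2, length.out = n)),
             site = site, stringsAsFactors = FALSE)
}

# small 1-site cohort, cheap enough for replicate loops
quick_cohort <- function(seed, truth_fn = planted_truth, ...) {
  design <- cohort_design(sites = "caecum", seed = seed)
  truth <- truth_fn(design, ...)
  co <- generate_counts(design, truth)
  j <- join_metadata(co$tables$caecum, co$metadata)
  list(design = design, truth = truth, table = co$tables$caecum,
       metadata = co$metadata, join = j, zero_fraction = co$zero_fraction)
}
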