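#!/usr/bin/env Rscript
# Event-count-weighted WPGMA clustering of the ssRNA molecules by Spearman
# similarity of their binding occupancy, and the corresponding rasterplot
# (row order emitted as TSV so the layout is checkable without pixels).

suppressPackageStartupMessages(library(smaccess))

out <- "results/analysis"
ann <- utils::read.table(file.path(out, "ssrna_h30_annotations.tsv"),
                         sep = "\t", header = TRUE)
events <- read_events(file.path(out, "ssrna_h30_events.tsv"))

om <- occupancy_matrix(events, ann, "H30", frame_period = 0.1, t0 = 25)
hc <- cluster_molecules(om, weighted = TRUE)
order_ids <- hc$labels[hc$order]

raster <- render_rasterplot(events, order_ids, reporters = "H30")
utils::write.table(raster$rows, file.path(out, "raster_row_order.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
dir.create(file.path(out, "figures"), showWarnings = FALSE)
ggplot2::ggsave(file.path(out, "figures", "ssrna_h30_raster.pdf"),
                raster$plot, width = 7, height = 5)
message(sprintf("clustered %d molecules; dendrogram heights %.3f .. %.3f",
                nrow(om$occupancy), min(hc$height), max(hc$height)))
message("raster row order and figure written under ", out)
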