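#!/usr/bin/env Rscript
# Stage 2: pre-treat the raw positions with the three quality filters
# (logger geometry, inside-lake viability, tag/bathymetry depth
# concordance) and report the exclusion accounting.

library(lakemorph)

out <- "results/analysis"
fixes <- read_positions(file.path(out, "positions.csv"))$fixes
bathy <- read_bathymetry(file.path(out, "bathymetry.asc"))
poly <- read_lake_polygon(file.path(out, "lake.geojson"))

pc <- pipeline_config()
qc <- run_qc(fixes, poly, bathy, pc)
print(qc$report)

write_positions(qc$valid, file.path(out, "positions_valid.csv"))
jsonlite::write_json(unclass(qc$report), file.path(out, "qc_report.json"),
                     auto_unbox = TRUE, digits = NA)
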