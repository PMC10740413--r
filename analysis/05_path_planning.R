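#!/usr/bin/env Rscript
# Stage 5 — toolpath planning with slow start and controlled overlap.
#
# Plans the 15 mm validation line and the 10 x 10 x 3 mm grid-filled prism
# (0.8 mm fill spacing, 0.5 mm frame offset, 0.3 mm short-edge overlap
# distance, 0.2 mm layers), applies the slow-start scheme (1 mm/s for 0.1 s
# at every printing resumption), books extruded volume at the solver's flow
# rate for the 8:4:3 ink at 250 kPa, and exports G-code.

library(inkflow)

dir.create("results", showWarnings = FALSE)
cfg <- path_config()

line <- plan_line(15, cfg)
cat("15 mm line:\n")
print(line)
cat(sprintf("  slow segment %.1f mm at %g mm/s, remainder %.1f mm at %g mm/s\n",
            segment_lengths(line)[1], cfg$slow_speed,
            segment_lengths(line)[2], cfg$speed))

prism <- plan_grid_prism(10, 10, layers = 15, cfg, pattern = "grid")
print(prism)
export_gcode(prism, "results/05_prism.gcode")

ink <- power_law_params(predict_n(c(8, 4, 3)), predict_K(c(8, 4, 3)))
sol <- solve_flow_rate(ink, default_nozzle_geometry(), 250)
book <- extrusion_bookkeeping(prism, sol$Q_ul_s)
write.csv(book, "results/05_prism_segments.csv", row.names = FALSE)

cat(sprintf("\n8:4:3 ink at 250 kPa: Q = %.3f uL/s -> filament d = %.3f mm at %g mm/s\n",
            sol$Q_ul_s, filament_diameter(sol$Q_ul_s, cfg$speed), cfg$speed))
cat(sprintf("Prism: %.1f mm printed, %.3f uL deposited over %.1f s printing, %d slow-start strokes\n",
            sum(book$length_mm[book$extruding]), sum(book$volume_ul),
            sum(book$time_s[book$extruding]), sum(book$slow_start)))
stopifnot(abs(sum(book$volume_ul) -
                sol$Q_ul_s * sum(book$time_s[book$extruding])) < 1e-9)
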