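#!/usr/bin/env Rscript
# Stage 5: WHO-target projections. Starting from the 2012 prevalences
# (carried unchanged to 2016), a gradual linear decrease reaching a 10%
# relative reduction by 2025 and 15% by 2030 is compared with a status-quo
# trajectory, over the 2016-2025 and 2016-2030 horizons.
suppressPackageStartupMessages(library(cvdpimex))
dir.create("results", showWarnings = FALSE)

bundle <- generate_inputs(seed = 20100, scale = 1)
t2 <- load_table2_fixture()

status_quo <- who_trajectory(t2, mid_reduction = 0, end_reduction = 0,
                             name = "status-quo")
who <- who_trajectory(t2, name = "who-targets")

message("WHO trajectory anchors (35-44 band):")
tr <- subset(who$trajectory, age_band == "35-44" & year %in% c(2016, 2025, 2030))
print(tr, row.names = FALSE)

d2025 <- compare_scenarios(bundle, status_quo, who, horizon = 10)  # 2016-2025
d2030 <- compare_scenarios(bundle, status_quo, who, horizon = 15)  # 2016-2030
write_results(d2025, "results", stem = "who_2025")
write_results(d2030, "results", stem = "who_2030")

message("\ncases averted by 2025 (10% relative reduction; negative = averted):")
print(format_delta_table(d2025), row.names = FALSE)
message("\ncases averted by 2030 (15% total relative reduction):")
print(format_delta_table(d2030), row.names = FALSE)
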