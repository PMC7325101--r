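#!/usr/bin/env Rscript
# Stage 2: generate the synthetic model-input bundle used by the later
# stages and record its headline structure. The national input tables
# behind the original model are not published, so the generator emulates
# them: population by sex and band, joint risk-factor strata, age-increasing
# base rates, bridge and history parameters, survey PI prevalences.
suppressPackageStartupMessages(library(cvdpimex))
dir.create("results", showWarnings = FALSE)

seed <- 20100
bundle <- generate_inputs(seed = seed, scale = 1)

pop <- aggregate(count ~ age_band, bundle$population, sum)
message("population by band (both sexes):")
print(pop, row.names = FALSE)

rates <- reshape(bundle$base_rates, idvar = c("sex", "age_band"),
                 timevar = "outcome", direction = "wide")
write.csv(rates, "results/base_rates.csv", row.names = FALSE)
write.csv(bundle$relative_risks, "results/relative_risks.csv",
          row.names = FALSE)
message("\nannual base rates (per person-year), male:")
print(subset(rates, sex == "male"), row.names = FALSE, digits = 3)
message("\nrelative risks (active vs inactive):")
print(bundle$relative_risks, row.names = FALSE)
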