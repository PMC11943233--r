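#!/usr/bin/env Rscript
# Step 3 -- advisory figures from the simulated cohort.
#
# (a) Blood and effect-site concentrations of one patient across the
#     whole case (rocuronium, sugammadex, complex, Ce_Rb);
# (b) the post-reversal window of the same patient, showing Ce_r, the
#     nadir and the rebound peak;
# (c) the distribution of Ce_r across the cohort;
# (d) Ce_r against the intraoperative target concentration.
#
# Usage: Rscript analysis/03_figures.R [patient_id]

library(recurasim)
library(ggplot2)

args <- commandArgs(trailingOnly = TRUE)
pid <- if (length(args)) as.integer(args[1]) else 1L
figdir <- "results/figures"
dir.create(figdir, showWarnings = FALSE, recursive = TRUE)

m <- utils::read.csv("results/cohort/metrics.csv")
tr <- utils::read.csv(sprintf("results/cohort/patients/trajectory_%03d.csv",
                              pid))

long <- rbind(
  data.frame(t = tr$time_s / 60, conc = tr$c_rb, series = "C_Rb (free)"),
  data.frame(t = tr$time_s / 60, conc = tr$c_sgx, series = "C_SGX (free)"),
  data.frame(t = tr$time_s / 60, conc = tr$c_comp, series = "C_complex"),
  data.frame(t = tr$time_s / 60, conc = tr$ce_rb, series = "Ce_Rb")
)
long <- long[long$conc > 0, ] # log scale: drop pre-dose zeros
ggsave(file.path(figdir, sprintf("patient_%03d_case.png", pid)),
       ggplot(long, aes(t, conc, colour = series)) +
         geom_line() +
         scale_y_log10() +
         labs(x = "time (min)", y = "concentration (ug/mL, log scale)",
              colour = NULL,
              title = sprintf("Patient %d: whole-case concentrations", pid)),
       width = 8, height = 4.5, dpi = 150)

mi <- m[m$id == pid, ]
sgx_t0 <- max(tr$time_s) - 60 * 60 # the reversal window is the last hour
rv <- tr[tr$time_s >= sgx_t0, ]
rv$t <- (rv$time_s - sgx_t0) / 60
ann <- data.frame(
  t = c(mi$t_r_min, mi$t_r_min + mi$t_min_min, mi$t_r_min + mi$t_max_min),
  ce = c(mi$ce_r, mi$ce_min, mi$ce_max),
  what = c("Ce_r (TOFR >= 0.9)", "nadir", "rebound peak")
)
ggsave(file.path(figdir, sprintf("patient_%03d_reversal.png", pid)),
       ggplot(rv, aes(t, ce_rb)) +
         geom_line() +
         geom_point(data = ann, aes(t, ce, colour = what), size = 2.5) +
         geom_hline(yintercept = mi$ce_r, linetype = 2, alpha = 0.5) +
         scale_y_log10() +
         labs(x = "time after sugammadex (min)",
              y = "Ce_Rb (ug/mL, log scale)", colour = NULL,
              title = sprintf("Patient %d: post-reversal free drug", pid)),
       width = 8, height = 4.5, dpi = 150)

ggsave(file.path(figdir, "ce_r_distribution.png"),
       ggplot(m, aes(ce_r)) +
         geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
         labs(x = "Ce_r (ug/mL)", y = "patients",
              title = "Recovery threshold concentration across the cohort"),
       width = 6, height = 4, dpi = 150)

ggsave(file.path(figdir, "ce_r_vs_target.png"),
       ggplot(m, aes(target_ce, ce_r)) +
         geom_point() +
         geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                     colour = "grey40") +
         labs(x = "intraoperative target Ce_Rb (ug/mL)",
              y = "Ce_r (ug/mL)",
              title = "Ce_r against the intraoperative target"),
       width = 6, height = 4, dpi = 150)

message("figures written to ", figdir, "/")
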