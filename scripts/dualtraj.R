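#!/usr/bin/env Rscript
# Thin command-line front end over the dualtraj package.
#
#   dualtraj.R simulate --n 2000 --seed 42 --out panel.csv --truth labels.csv
#   dualtraj.R fit      --panel panel.csv --channel depression --groups 4
#                       --order 1 --seed 7 --out fit.json
#   dualtraj.R select   --panel panel.csv --channel anxiety --jmin 2 --jmax 5
#                       --seed 7 --out selection.csv
#   dualtraj.R dual     --panel panel.csv --groups1 4 --groups2 4 --seed 7
#                       --out dualfit.json
#   dualtraj.R run      --config pipeline.yaml

suppressMessages(library(dualtraj))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: dualtraj.R <simulate|fit|select|dual|run> ...")
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- which(args == paste0("--", flag))
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

if (cmd == "simulate") {
  cfg <- khps_preset(N = as.integer(opt("n", "3983")))
  sim <- generate_dual_panel(cfg, seed = as.integer(opt("seed", "1")))
  write_panel(sim$panel, opt("out", "panel.csv"))
  truth <- opt("truth")
  if (!is.null(truth)) write.csv(sim$labels, truth, row.names = FALSE)

} else if (cmd == "fit") {
  panel <- read_panel(opt("panel"))
  f <- gbtm_fit(panel, opt("channel", "depression"),
                J = as.integer(opt("groups", "4")),
                order = as.integer(opt("order", "1")),
                seed = as.integer(opt("seed", "1")))
  print(f)
  jsonlite::write_json(list(
    channel = f$channel, J = f$params$J, order = f$params$order,
    beta = f$params$beta, pi = f$params$pi, loglik = f$loglik,
    bic_traj = f$bic_traj, aic_traj = f$aic_traj, app = f$app,
    converged = f$converged
  ), opt("out", "fit.json"), auto_unbox = TRUE, digits = NA,
  matrix = "rowmajor")

} else if (cmd == "select") {
  panel <- read_panel(opt("panel"))
  g <- fit_grid(panel, opt("channel", "depression"),
                J_range = seq(as.integer(opt("jmin", "2")),
                              as.integer(opt("jmax", "5"))),
                seed = as.integer(opt("seed", "1")))
  print(g)
  cat("selected:", select_best(g), "groups\n")
  write.csv(g$table, opt("out", "selection.csv"), row.names = FALSE)

} else if (cmd == "dual") {
  panel <- read_panel(opt("panel"))
  f <- dual_fit(panel, as.integer(opt("groups1", "4")),
                as.integer(opt("groups2", "4")),
                order = as.integer(opt("order", "1")),
                seed = as.integer(opt("seed", "1")))
  print(f)
  jsonlite::write_json(list(
    channels = f$channels, J = f$params$J, K = f$params$K,
    beta1 = f$params$beta1, beta2 = f$params$beta2,
    joint_pi = f$params$joint_pi,
    cond_2_given_1 = f$cond_2_given_1, cond_1_given_2 = f$cond_1_given_2,
    loglik = f$loglik, bic_traj = f$bic_traj, converged = f$converged
  ), opt("out", "dualfit.json"), auto_unbox = TRUE, digits = NA,
  matrix = "rowmajor")

} else if (cmd == "run") {
  man <- run_pipeline(read_pipeline_config(opt("config")))
  cat("artifacts written:", length(man$artifacts), "\n")

} else {
  stop("unknown command: ", cmd)
}
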