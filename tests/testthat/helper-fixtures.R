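# shared small fixtures, built in code at test time

two_well_landscape <- function(depths = c(10, 5), width = 0.3,
                               temperature = 350) {
  make_landscape(
    c("cv1"),
    wells = list(list(center = 1.5, depth = depths[1], width = width),
                 list(center = 4.5, depth = depths[2], width = width)),
    domain = list(c(0, 6)), temperature = temperature)
}

two_cv_landscape <- function() {
  make_landscape(
    c("cv1", "cv2"),
    wells = list(list(center = c(1.6, 1.5), depth = 25, width = 0.55),
                 list(center = c(3.4, 3.2), depth = 17, width = 0.5),
                 list(center = c(1.5, 3.4), depth = 14, width = 0.45)),
    domain = list(c(0, 5), c(0, 5)))
}

# replica_run with known frame CVs and an optional analytic bias
manual_run <- function(id, cvs, bias_fun = NULL, biased_cv = names(cvs)[1],
                       grid = seq(0, 6, by = 0.05)) {
  cv_table <- data.frame(time = seq_len(nrow(as.data.frame(cvs))),
                         as.data.frame(cvs))
  bias <- if (is.null(bias_fun)) rep(0, length(grid)) else bias_fun(grid)
  replica_run(id = id, biased_cv = biased_cv, cv_table = cv_table,
              bias_grid = data.frame(cv_value = grid, bias = bias))
}
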