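#' Write a recording as delimited text with a JSON sidecar
#'
#' Traces go to `path` as tab-separated text with a units-bearing header
#' (`t_ms, I_com_nA, I_inj_nA, V_m_mV, V_total_mV, V_amp_mV`); the
#' configuration, spike times and seed go to `<path>.json`. The numeric
#' payload round-trips through [read_trace()].
#'
#' @param recording A [record()] result with traces.
#' @param path Output file path.
#' @param digits Significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_trace <- function(recording, path, digits = 10) {
  df <- as.data.frame(recording)
  df <- as.data.frame(lapply(df, signif, digits = digits))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- list(
    mode = recording$amp$mode, dcc_rate = recording$amp$dcc_rate,
    duty = recording$amp$duty, sample_offset = recording$amp$sample_offset,
    bridge_balance = recording$amp$bridge_balance,
    dt = recording$dt, seed = recording$seed,
    spike_times = recording$spike_times,
    neuron = unclass(recording$neuron),
    electrode = if (!is.null(recording$electrode))
      unclass(recording$electrode),
    stimulus = recording$stim$segments)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a delimited trace file
#'
#' Reads tab- or comma-separated traces written by [write_trace()] or
#' recorded externally. Requires at least a time column (`t_ms`) and a
#' voltage column (`V_amp_mV`, `V_m_mV` or a bare `V_mV`); a missing
#' current column is treated as no injected current. When a `<path>.json`
#' sidecar exists its spike times and configuration are attached.
#'
#' @param path File path.
#' @return A list of class `dcc_trace` with elements `time`, `I_com`,
#'   `V` (the analysis voltage), all columns found, `dt`, and (if present)
#'   `spike_times` and `config` from the sidecar.
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!"t_ms" %in% names(df))
    stop("trace file is missing required column 't_ms'")
  vcol <- intersect(c("V_amp_mV", "V_m_mV", "V_mV"), names(df))
  if (length(vcol) == 0)
    stop("trace file is missing a voltage column ",
         "(one of V_amp_mV, V_m_mV, V_mV)")
  icol <- intersect(c("I_com_nA", "I_nA"), names(df))
  out <- list(time = df$t_ms,
              I_com = if (length(icol)) df[[icol[1]]] else
                rep(0, nrow(df)),
              V = df[[vcol[1]]],
              columns = df,
              dt = stats::median(diff(df$t_ms)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    cfg <- jsonlite::read_json(side, simplifyVector = TRUE)
    out$spike_times <- as.numeric(unlist(cfg$spike_times))
    out$config <- cfg
  }
  class(out) <- "dcc_trace"
  out
}

#' Assemble and serialize a run configuration
#'
#' A run configuration bundles everything needed to reproduce one
#' simulation: neuron, electrode, amplifier, stimulus, integration step and
#' seed. [write_run_config()]/[read_run_config()] round-trip it losslessly
#' through YAML.
#'
#' @param neuron A [cell_params()] or [lif_params()].
#' @param electrode An [electrode_params()] or `NULL`.
#' @param amp An [amplifier_config()].
#' @param stim A [stimulus()].
#' @param dt Optional integration step, ms.
#' @param seed Optional RNG seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(neuron, electrode = NULL, amp, stim, dt = NULL,
                       seed = NULL) {
  stopifnot(inherits(neuron, c("cell_params", "lif_params")),
            inherits(amp, "amp_config"), inherits(stim, "stimulus"))
  structure(list(neuron = neuron, electrode = electrode, amp = amp,
                 stim = stim, dt = dt, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    neuron = c(list(kind = if (inherits(config$neuron, "lif_params"))
      "lif" else "passive"), unclass(config$neuron)),
    electrode = if (!is.null(config$electrode))
      unclass(config$electrode),
    amplifier = unclass(config$amp),
    stimulus = lapply(seq_len(nrow(config$stim$segments)), function(i)
      as.list(config$stim$segments[i, ])),
    dt = config$dt, seed = config$seed)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  nn <- x$neuron
  neuron <- if (identical(nn$kind, "lif")) {
    lif_params(G_in = nn$G_in, tau_m = nn$tau_m, V_r = nn$V_r,
               V_th = nn$V_th, g_ahp_max = nn$g_ahp_max, E_K = nn$E_K,
               tau_ahp = nn$tau_ahp, alpha = nn$alpha, sigma = nn$sigma,
               V_reset = nn$V_reset, t_refractory = nn$t_refractory,
               spike_peak = nn$spike_peak, spike_width = nn$spike_width)
  } else {
    cell_params(G_in = nn$G_in, tau_m = nn$tau_m, V0 = nn$V0)
  }
  electrode <- if (!is.null(x$electrode))
    electrode_params(G_e = x$electrode$G_e, tau_e = x$electrode$tau_e)
  amp <- amplifier_config(x$amplifier$mode,
                          dcc_rate = x$amplifier$dcc_rate,
                          duty = x$amplifier$duty,
                          sample_offset = x$amplifier$sample_offset,
                          bridge_balance = x$amplifier$bridge_balance)
  stim <- stimulus(do.call(rbind, lapply(x$stimulus, as.data.frame)))
  run_config(neuron, electrode, amp, stim, dt = x$dt, seed = x$seed)
}

#' Execute a run configuration
#'
#' @param config A [run_config()].
#' @param ... Passed to [record()].
#' @return A [record()] result.
#' @export
run_simulation <- function(config, ...) {
  stopifnot(inherits(config, "run_config"))
  record(config$neuron, config$electrode, config$amp, config$stim,
         dt = config$dt, seed = config$seed, ...)
}
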