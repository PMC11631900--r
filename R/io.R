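# Plain-text serialisation of model parameters and traces.

#' Write / read an ionic-model parameter table as a key-value file
#'
#' @param model An `ionic_model`.
#' @param path File path.
#' @export
write_model_params <- function(model, path) {
  stopifnot(inherits(model, "ionic_model"))
  lines <- c(sprintf("# cell_type: %s", model$cell_type),
             sprintf("# severity: %s", model$ischaemia$severity),
             sprintf("%s = %.17g", names(model$parameters), model$parameters))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_params
#' @return For the reader, a named numeric parameter vector.
#' @export
read_model_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  p <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
  names(p) <- vapply(kv, `[`, character(1), 1)
  p[vfib_par_names]
}

#' Write an action-potential trace as columnar text
#'
#' Columns: `time_ms`, `Vm_mV`, `Cai_uM`.
#' @param trace An `ap_trace`.
#' @param path File path.
#' @export
write_ap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ap_trace"))
  d <- data.frame(time_ms = trace$time, Vm_mV = trace$Vm, Cai_uM = trace$Cai)
  write.table(d, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_ap_trace
#' @export
read_ap_trace <- function(path) {
  d <- read.table(path, header = TRUE)
  structure(list(time = d$time_ms, Vm = d$Vm_mV, Cai = d$Cai_uM,
                 stim_times = numeric(0),
                 final_state = NULL,
                 record_dt = if (nrow(d) > 1) diff(d$time_ms[1:2]) else NA),
            class = "ap_trace")
}
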