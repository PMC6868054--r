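# Plain-text serialization. All formats are line-oriented text: spike
# trains as two-column tables, probability tables as (bitstring, p) pairs,
# networks and sampling-network descriptions as YAML with units in the
# field names, image datasets as CSV.

unitColMap <- c(V_reset = "V_reset_mV", E_leak = "E_leak_mV",
                V_thresh = "V_thresh_mV", E_inh = "E_inh_mV",
                E_exc = "E_exc_mV", tau_ref = "tau_ref_ms",
                tau_mem = "tau_mem_ms", C_mem = "C_mem_nF",
                tau_syn_exc = "tau_syn_exc_ms", tau_syn_inh = "tau_syn_inh_ms",
                weight = "weight_nS", delay = "delay_ms")

renameCols <- function(df, map) {
  i <- match(names(df), names(map))
  names(df)[!is.na(i)] <- map[i[!is.na(i)]]
  df
}

#' Read and write spikesampler objects as plain text
#'
#' Round-trip serialization: [SpikeTrain-class] as a two-column table
#' (time_ms, neuron) with the window length in a header comment;
#' [ProbabilityTable-class] as (state bitstring, probability) pairs, unit 1
#' leftmost; [NetworkDefinition-class] as YAML with units in the field
#' names; [ImageDataset-class] as CSV (label, split, 144 pixel columns);
#' [SamplingNetwork-class] as YAML carrying the constructor arguments,
#' digital weights and calibration results. Reading returns a semantically
#' identical object (exact for integers and bit patterns, to double
#' precision for reals).
#'
#' @param x object to write.
#' @param path file path.
#' @return the read functions return the reconstructed object; write
#'   functions return \code{invisible(path)}.
#' @name serialization
#' @export
writeSpikeTrain <- function(x, path) {
  stopifnot(is(x, "SpikeTrain"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_ms: %.17g", x@duration), con)
  writeLines("time_ms\tneuron", con)
  if (length(x@times))
    writeLines(sprintf("%.17g\t%d", x@times, x@ids), con)
  invisible(path)
}

#' @rdname serialization
#' @export
readSpikeTrain <- function(path) {
  first <- readLines(path, n = 1L)
  dur <- as.numeric(sub("# duration_ms: ", "", first, fixed = TRUE))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  spikeTrain(df$time_ms, as.integer(df$neuron), duration = dur)
}

#' @rdname serialization
#' @export
writeProbabilityTable <- function(x, path) {
  stopifnot(is(x, "ProbabilityTable"))
  Z <- stateMatrix(x@n)
  bits <- apply(Z, 1L, paste0, collapse = "")
  utils::write.table(data.frame(state = bits, p = sprintf("%.17g", x@p)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname serialization
#' @export
readProbabilityTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  n <- nchar(df$state[1])
  idx <- vapply(strsplit(df$state, ""), function(b)
    sum(as.integer(b) * 2^(seq_len(n) - 1)), numeric(1)) + 1
  p <- numeric(2^n)
  p[idx] <- df$p
  probabilityTable(p, n)
}

#' @rdname serialization
#' @export
writeNetwork <- function(x, path) {
  stopifnot(is(x, "NetworkDefinition"))
  obj <- list(
    neurons = renameCols(x@neurons, unitColMap),
    synapses = renameCols(x@synapses, unitColMap),
    extSynapses = renameCols(x@extSynapses, unitColMap),
    ports = as.list(x@ports))
  yaml::write_yaml(obj, path, column.major = FALSE, precision = 17L)
  invisible(path)
}

#' @rdname serialization
#' @export
readNetwork <- function(path) {
  obj <- yaml::read_yaml(path)
  back <- stats::setNames(names(unitColMap), unitColMap)
  fromRows <- function(rows, template) {
    if (!length(rows)) return(template)
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    renameCols(df, back)
  }
  neurons <- fromRows(obj$neurons, NULL)
  if (is.null(neurons)) stopf("network file has no neurons: %s", path)
  syn <- fromRows(obj$synapses, emptySynapses())
  ext <- fromRows(obj$extSynapses, emptyExtSynapses())
  syn$pre <- as.integer(syn$pre); syn$post <- as.integer(syn$post)
  ext$post <- as.integer(ext$post)
  networkDefinition(neurons, syn, ext, ports = unlist(obj$ports))
}

#' @rdname serialization
#' @export
writeImageDataset <- function(x, path) {
  stopifnot(is(x, "ImageDataset"))
  df <- data.frame(label = x@labels, split = x@split, x@images)
  names(df)[-(1:2)] <- sprintf("px%03d", seq_len(ncol(x@images)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname serialization
#' @export
readImageDataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  img <- as.matrix(df[, grepl("^px", names(df)), drop = FALSE])
  storage.mode(img) <- "integer"
  dimnames(img) <- NULL
  new("ImageDataset", images = img, labels = as.integer(df$label),
      split = df$split, nClasses = max(as.integer(df$label)),
      prototypes = matrix(0L, max(as.integer(df$label)), ncol(img)))
}

#' @rdname serialization
#' @export
writeSamplingNetwork <- function(x, path) {
  stopifnot(is(x, "SamplingNetwork"))
  obj <- list(
    nUnits = nUnits(x),
    noise = x@noise[setdiff(names(x@noise), "rnIds")],
    unitScale_nS = x@unitScale,
    sharedBias = length(unique(x@biasIds)) == 1L && nUnits(x) > 1L,
    substrateSeed = x@substrateSeed,
    variability = list(cvWeightFixed = x@variability@cvWeightFixed,
                       cvTauSynFixed = x@variability@cvTauSynFixed,
                       cvWeightTrial = x@variability@cvWeightTrial),
    layout = x@layout,
    kappa = x@kappa,
    fits = lapply(x@fits, function(f)
      list(nu0_Hz = f@nu0, wb0 = f@wb0, s = f@s)),
    biasDigital = x@biasDigital,
    couplingDigital = apply(x@couplingDigital, 1L, identity,
                            simplify = FALSE))
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname serialization
#' @export
readSamplingNetwork <- function(path) {
  o <- yaml::read_yaml(path)
  vm <- variabilityModel(o$variability$cvWeightFixed,
                         o$variability$cvTauSynFixed,
                         o$variability$cvWeightTrial)
  args <- list(noise = o$noise$type, noiseRate = o$noise$rate,
               noiseWeight = o$noise$weight, unitScale = o$unitScale_nS,
               variability = vm, substrateSeed = o$substrateSeed)
  if (!is.null(o$noise$rnSpec))
    args$rnSpec <- do.call(randomNetworkSpec, o$noise$rnSpec[
      c("nR", "kRN", "kNoise", "wRN", "wProj")])
  ssn <- if (identical(o$layout$type, "hierarchical")) {
    do.call(buildHierarchicalNetwork,
            c(list(nVisible = length(o$layout$visible),
                   nHidden = length(o$layout$hidden),
                   nLabels = length(o$layout$label),
                   sharedBias = o$sharedBias), args))
  } else {
    do.call(buildSamplingNetwork,
            c(list(nUnits = o$nUnits, sharedBias = o$sharedBias), args))
  }
  W <- do.call(rbind, lapply(o$couplingDigital, as.numeric))
  ssn <- setDigitalWeights(ssn, as.numeric(o$biasDigital), W)
  if (length(o$fits))
    ssn@fits <- lapply(o$fits, function(f)
      new("ActivationFit", nu0 = f$nu0_Hz, wb0 = f$wb0, s = f$s))
  if (length(o$kappa)) ssn@kappa <- as.numeric(o$kappa)
  ssn
}
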