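#' Save a network in the native structured-text model format
#'
#' Line-oriented plain-text format:
#' \preformatted{
#' model <name>
#' volume <number>
#' units <label>
#' avogadro <true|false>
#' species <id> amount=<int>|conc=<number> [diffusion=<number>]
#' reaction <lhs> -> <rhs> : c=<number>|k=<number> [delay=<number>] [consuming=<true|false>]
#' }
#' Reaction sides use `"2 R7 + S0"` style terms with `0` for the
#' source/sink. `c=` marks a pre-scaled specific rate, `k=` a macroscopic
#' rate converted at build time. Blank lines and `#` comments are ignored.
#' A save/load round trip reproduces an equivalent network (identical
#' species, counts and rates).
#'
#' @param net A [ReactionNetwork-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
saveModel <- function(net, path) {
  side <- function(v) {
    if (length(v) == 0L) return("0")
    paste(ifelse(v > 1L, paste(v, names(v)), names(v)), collapse = " + ")
  }
  lines <- c(
    "# ppsim native model",
    paste("model", net@name),
    paste("volume", format(net@volume, digits = 17)),
    paste("units", net@units),
    paste("avogadro", tolower(as.character(net@avogadroScaling))))
  for (i in seq_along(net@species)) {
    ln <- paste0("species ", net@species[i], " amount=", net@initialCounts[i])
    if (!is.na(net@diffusion[i]))
      ln <- paste0(ln, " diffusion=", format(net@diffusion[i], digits = 17))
    lines <- c(lines, ln)
  }
  for (rx in net@reactions) {
    tag <- if (rx@rateIsSpecific) "c" else "k"
    ln <- paste0("reaction ", side(rx@reactants), " -> ", side(rx@products),
                 " : ", tag, "=", format(rx@rate, digits = 17))
    if (!is.na(rx@delay))
      ln <- paste0(ln, " delay=", format(rx@delay, digits = 17),
                   " consuming=", tolower(as.character(rx@delayConsuming)))
    lines <- c(lines, ln)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a network from the native model format
#'
#' Parse errors report the offending line number. See [saveModel()] for
#' the format.
#'
#' @param path File path, or a `"builtin:<name>"` model reference (see
#'   [builtinModel()]).
#' @return A validated [ReactionNetwork-class].
#' @export
loadModel <- function(path) {
  if (grepl("^builtin:", path)) return(builtinModel(path))
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  name <- "model"; volume <- 1; units <- "s"; avogadro <- FALSE
  spec <- list(); rxns <- list()
  perr <- function(i, ...) stop("parse error at line ", i, ": ", ...)
  kvPairs <- function(s, i) {
    if (!nzchar(trimws(s))) return(list())
    toks <- strsplit(trimws(s), "\\s+")[[1]]
    out <- list()
    for (tk in toks) {
      kv <- strsplit(tk, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) perr(i, "expected key=value, got '", tk, "'")
      out[[kv[1]]] <- kv[2]
    }
    out
  }
  num <- function(x, i, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) perr(i, "non-numeric ", what, ": '", x, "'")
    v
  }
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*", "", lines[i]))
    if (!nzchar(ln)) next
    kw <- sub("\\s.*", "", ln)
    rest <- trimws(sub("^\\S+\\s*", "", ln))
    if (kw == "model") name <- rest
    else if (kw == "volume") volume <- num(rest, i, "volume")
    else if (kw == "units") units <- rest
    else if (kw == "avogadro") avogadro <- tolower(rest) %in% c("true", "yes", "1")
    else if (kw == "species") {
      id <- sub("\\s.*", "", rest)
      kv <- kvPairs(sub("^\\S+\\s*", "", rest), i)
      row <- list(id = id, amount = NA_real_, conc = NA_real_,
                  diffusion = NA_real_)
      if (!is.null(kv$amount)) row$amount <- num(kv$amount, i, "amount")
      if (!is.null(kv$conc)) row$conc <- num(kv$conc, i, "concentration")
      if (!is.null(kv$diffusion)) row$diffusion <- num(kv$diffusion, i, "diffusion constant")
      if (is.na(row$amount) == is.na(row$conc))
        perr(i, "species '", id, "' needs exactly one of amount= or conc=")
      spec[[length(spec) + 1L]] <- row
    } else if (kw == "reaction") {
      parts <- strsplit(rest, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L) perr(i, "reaction needs '<sides> : <rate...>'")
      sides <- tryCatch(parseReactionString(parts[1]),
                        error = function(e) perr(i, conditionMessage(e)))
      kv <- kvPairs(parts[2], i)
      specific <- !is.null(kv$c)
      rateStr <- if (specific) kv$c else kv$k
      if (is.null(rateStr)) perr(i, "reaction needs a rate (c= or k=)")
      rate <- num(rateStr, i, "rate")
      delay <- if (!is.null(kv$delay)) num(kv$delay, i, "delay") else NA_real_
      consuming <- if (!is.null(kv$consuming))
        tolower(kv$consuming) %in% c("true", "yes", "1") else TRUE
      rxns[[length(rxns) + 1L]] <-
        reaction(sides$reactants, sides$products, rate = rate,
                 specific = specific, delay = delay, consuming = consuming)
    } else perr(i, "unknown keyword '", kw, "'")
  }
  if (length(spec) == 0L) stop("model file declares no species: ", path)
  df <- do.call(rbind, lapply(spec, as.data.frame))
  net <- reactionNetwork(df, rxns, volume = volume,
                         avogadroScaling = avogadro, name = name,
                         units = units)
  repv <- validateNetwork(net)
  if (length(repv)) stop("invalid model in ", path, ": ",
                         paste(repv, collapse = "; "))
  net
}
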