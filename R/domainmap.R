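# Domain maps: named residue ranges per chain, and selections derived from
# them. Residue numbers follow the input file verbatim (crystal numbering).

#' Build a domain map
#'
#' @param ... named entries. Each entry is either a string
#'   `"chain:start-end"` (several ranges comma-separated,
#'   `"A:1-10,B:5-20"`), or a data.frame with columns `chain`, `start`, `end`.
#' @return a [DomainMap-class]
#' @examples
#' domainMap(nSH2 = "B:322-428", helical = "A:526-643")
#' @export
domainMap <- function(...) {
  args <- list(...)
  entries <- lapply(args, function(x) {
    if (is.data.frame(x)) return(x[, c("chain", "start", "end")])
    .parseRangeSpec(x)
  })
  new("DomainMap", entries = entries)
}

.parseRangeSpec <- function(txt) {
  parts <- trimws(strsplit(txt, ",")[[1L]])
  parsed <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([A-Za-z0-9]+):(-?[0-9]+)-(-?[0-9]+)$", p))[[1L]]
    if (length(m) != 4L)
      stop("cannot parse range '", p, "' (expected chain:start-end)")
    data.frame(chain = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parsed)
}

#' Read a domain map from a config file
#'
#' Plain-text schema: one `name = chain:start-end[, chain:start-end]` entry
#' per line; blank lines and `#` comments ignored. A fixture for the PI3Kalpha
#' p110alpha(A)/p85alpha(B) heterodimer ships with the package:
#' `system.file("extdata", "pi3ka_domains.cfg", package = "trajnet")`.
#'
#' @param path config file path
#' @return a [DomainMap-class]
#' @export
readDomainMap <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  entries <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop("cannot parse domain-map line: ", ln)
    entries[[trimws(kv[2L])]] <- .parseRangeSpec(trimws(kv[3L]))
  }
  new("DomainMap", entries = entries)
}

#' Write a domain map config file
#'
#' @param map a [DomainMap-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeDomainMap <- function(map, path) {
  stopifnot(is(map, "DomainMap"))
  lines <- vapply(names(map@entries), function(nm) {
    d <- map@entries[[nm]]
    sprintf("%s = %s", nm,
            paste(sprintf("%s:%d-%d", d$chain, d$start, d$end), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Select the atoms of a named domain
#'
#' Resolves a domain-map entry against a topology and returns the selected
#' atoms in residue order, restricted to the requested atom subset.
#'
#' @param topology a [Topology-class]
#' @param map a [DomainMap-class]
#' @param name entry name in `map`
#' @param atomSubset `"all"`, `"heavy"` (non-hydrogen) or `"CA"`
#' @return a [ResidueSelection-class]
#' @export
selectDomain <- function(topology, map, name, atomSubset = c("all", "heavy", "CA")) {
  stopifnot(is(topology, "Topology"), is(map, "DomainMap"))
  atomSubset <- match.arg(atomSubset)
  if (!name %in% names(map@entries))
    stop("key error: domain '", name, "' not in map (have: ",
         paste(names(map@entries), collapse = ", "), ")")
  ranges <- map@entries[[name]]
  a <- topology@atoms
  inDomain <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(ranges)))
    inDomain <- inDomain | (a$chain == ranges$chain[i] &
                            a$resno >= ranges$start[i] & a$resno <= ranges$end[i])
  keep <- inDomain & switch(atomSubset,
    all = TRUE,
    heavy = a$element != "H",
    CA = a$name == "CA")
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("empty-selection error: domain '", name,
         "' resolves to zero atoms for subset '", atomSubset, "'")
  # residue order: by chain (file order), then residue number, then file order
  ord <- order(match(a$chain[idx], unique(a$chain)), a$resno[idx], idx)
  idx <- idx[ord]
  key <- !duplicated(paste(a$chain[idx], a$resno[idx]))
  new("ResidueSelection", atomIndices = as.integer(idx), domain = name,
      residues = data.frame(chain = a$chain[idx][key], resno = a$resno[idx][key],
                            resname = a$resname[idx][key], stringsAsFactors = FALSE))
}

#' Ad-hoc residue selection
#'
#' Selects residues of one chain by number range without a domain map; useful
#' for single residues (e.g. the mutation site) and short helices.
#'
#' @param topology a [Topology-class]
#' @param chain chain id
#' @param from,to inclusive residue-number range
#' @param atomSubset `"all"`, `"heavy"` or `"CA"`
#' @param name label for the selection
#' @return a [ResidueSelection-class]
#' @export
selectResidues <- function(topology, chain, from, to = from,
                           atomSubset = c("all", "heavy", "CA"),
                           name = sprintf("%s:%d-%d", chain, from, to)) {
  atomSubset <- match.arg(atomSubset)
  map <- domainMap(sel = data.frame(chain = chain, start = as.integer(from),
                                    end = as.integer(to), stringsAsFactors = FALSE))
  names(map@entries) <- name
  selectDomain(topology, map, name, atomSubset)
}
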