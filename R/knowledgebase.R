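#' Parse a KGML pathway map
#'
#' Reads a KEGG Markup Language document into a [PathwayMap-class]. Entry
#' elements become entry nodes (KO identifiers are taken from
#' whitespace-separated \code{ko:Kxxxxx} tokens of the \code{name}
#' attribute, compound identifiers from \code{cpd:Cxxxxx} tokens); each
#' \code{relation} and \code{reaction} element becomes one knowledge record
#' with its endpoints resolved from entry ids to KO sets. Compound subtypes
#' of relations are resolved through the compound entry they reference.
#'
#' Relations or reactions whose endpoints reference an unknown entry id, or
#' resolve to an empty KO set (e.g. linking a map-type placeholder node),
#' are skipped; one warning reports the count, which is also kept in the
#' \code{nSkipped} slot.
#'
#' A KGML \code{reaction} element names a single catalysing entry together
#' with substrate and product compounds; its record therefore carries the
#' catalyst's KO set on both sides and contributes its compounds to
#' [attachCompounds()].
#'
#' @param x path to a KGML file, or a single string of KGML/XML text.
#' @return a [PathwayMap-class]
#' @examples
#' kgml <- paste0(
#'  '<pathway name="path:map99999" title="demo">',
#'  '<entry id="1" name="ko:K00001" type="ortholog"/>',
#'  '<entry id="2" name="ko:K00002" type="ortholog"/>',
#'  '<relation entry1="1" entry2="2" type="ECrel"/></pathway>')
#' pm <- parseKGML(kgml)
#' records(pm)
#' @export
parseKGML <- function(x) {
  doc <- xml2::read_xml(x)
  root <- xml2::xml_name(doc)
  if (root != "pathway")
    stop("not a KGML document: root element is <", root, ">")
  map_id <- sub("^path:", "", xml2::xml_attr(doc, "name"))
  if (is.na(map_id) || map_id == "") map_id <- "unknown"

  ent_nodes <- xml2::xml_find_all(doc, "./entry")
  entry_id <- xml2::xml_attr(ent_nodes, "id")
  etype <- xml2::xml_attr(ent_nodes, "type")
  enames <- xml2::xml_attr(ent_nodes, "name")
  tok <- strsplit(ifelse(is.na(enames), "", enames), "[[:space:]]+")
  ko_ids <- lapply(tok, function(t) {
    k <- sub("^ko:", "", t[grepl("^ko:K[0-9]{5}$", t)])
    sort(unique(k))
  })
  cpd_id <- vapply(tok, function(t) {
    c_ <- sub("^cpd:", "", t[grepl("^cpd:C[0-9]{5}$", t)])
    if (length(c_)) c_[1L] else NA_character_
  }, NA_character_)
  node_kind <- ifelse(etype %in% c("ortholog", "enzyme", "gene") &
                        lengths(ko_ids) > 0L, "enzyme",
               ifelse(etype == "compound", "compound",
               ifelse(etype == "map", "map", "other")))
  entries <- data.frame(entry_id = entry_id, node_kind = node_kind,
                        compound_id = cpd_id, stringsAsFactors = FALSE)
  entries$ko_ids <- ko_ids

  ko_of <- function(id) {
    i <- match(id, entry_id)
    if (is.na(i)) NULL else ko_ids[[i]]
  }
  cpd_of_entry <- function(id) {
    i <- match(id, entry_id)
    if (is.na(i)) NA_character_ else cpd_id[i]
  }

  ups <- list(); dns <- list(); typs <- character(0); cpds <- list()
  n_skipped <- 0L

  for (rel in xml2::xml_find_all(doc, "./relation")) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    u <- ko_of(e1); d <- ko_of(e2)
    if (is.null(u) || is.null(d) || !length(u) || !length(d)) {
      n_skipped <- n_skipped + 1L
      next
    }
    sub_vals <- xml2::xml_attr(
      xml2::xml_find_all(rel, "./subtype[@name='compound']"), "value")
    cc <- character(0)
    for (v in sub_vals) {
      if (grepl("^C[0-9]{5}$", v)) cc <- c(cc, v)
      else {
        ci <- cpd_of_entry(v)
        if (!is.na(ci)) cc <- c(cc, ci)
      }
    }
    ups <- c(ups, list(u)); dns <- c(dns, list(d))
    typs <- c(typs, xml2::xml_attr(rel, "type"))
    cpds <- c(cpds, list(sort(unique(cc))))
  }

  for (rxn in xml2::xml_find_all(doc, "./reaction")) {
    rid <- xml2::xml_attr(rxn, "id")
    k <- ko_of(rid)
    if (is.null(k) || !length(k)) {
      # fall back to entries advertising this reaction name
      rname <- xml2::xml_attr(rxn, "name")
      own <- xml2::xml_attr(ent_nodes, "reaction")
      hit <- which(!is.na(own) & !is.na(rname) &
                     vapply(strsplit(ifelse(is.na(own), "", own),
                                     "[[:space:]]+"),
                            function(t) rname %in% t, NA))
      k <- sort(unique(unlist(ko_ids[hit], use.names = FALSE)))
    }
    if (!length(k)) {
      n_skipped <- n_skipped + 1L
      next
    }
    subs <- sub("^cpd:", "", xml2::xml_attr(
      xml2::xml_find_all(rxn, "./substrate"), "name"))
    prods <- sub("^cpd:", "", xml2::xml_attr(
      xml2::xml_find_all(rxn, "./product"), "name"))
    cc <- sort(unique(c(subs, prods)))
    cc <- cc[grepl("^C[0-9]{5}$", cc)]
    ups <- c(ups, list(k)); dns <- c(dns, list(k))
    typs <- c(typs, "reaction")
    cpds <- c(cpds, list(cc))
  }

  recs <- data.frame(record_type = typs,
                     source_map = rep(map_id, length(typs)),
                     stringsAsFactors = FALSE)
  recs$upstream <- ups
  recs$downstream <- dns
  recs$compounds <- cpds
  recs <- recs[, c("upstream", "downstream", "record_type", "compounds",
                   "source_map"), drop = FALSE]

  if (n_skipped > 0L)
    warning("skipped ", n_skipped,
            " relation/reaction element(s) with unresolvable endpoints in ",
            map_id)

  new("PathwayMap", mapId = map_id, entries = entries, records = recs,
      nSkipped = n_skipped)
}

.emptyRecords <- function() {
  r <- data.frame(record_type = character(0), source_map = character(0),
                  stringsAsFactors = FALSE)
  r$upstream <- list(); r$downstream <- list(); r$compounds <- list()
  r[, c("upstream", "downstream", "record_type", "compounds", "source_map")]
}

#' Build a relation knowledgebase from parsed pathway maps
#'
#' Pools the relation/reaction records of all maps and indexes every
#' ordered KO pair \code{(u, d)} with \code{u} in a record's upstream set
#' and \code{d} in its downstream set. Records duplicated across maps are
#' retained for provenance but collapse onto the same index entry.
#'
#' @param maps a list of [PathwayMap-class] objects (or a single one).
#' @param excludeMaps character vector of map ids whose records are left
#'   out, e.g. to withhold the target organism's own pathways.
#' @return a [RelationKnowledgebase-class]
#' @export
buildKnowledgebase <- function(maps, excludeMaps = character(0)) {
  if (is(maps, "PathwayMap")) maps <- list(maps)
  if (!length(maps)) stop("at least one pathway map is required")
  keep <- Filter(function(m) !(m@mapId %in% excludeMaps), maps)
  recs <- do.call(rbind, c(list(.emptyRecords()),
                           lapply(keep, function(m) m@records)))
  rownames(recs) <- NULL
  idx <- new.env(parent = emptyenv())
  if (nrow(recs)) {
    for (i in seq_len(nrow(recs))) {
      pairs <- expand.grid(u = recs$upstream[[i]], d = recs$downstream[[i]],
                           stringsAsFactors = FALSE)
      for (k in .edgeKey(pairs$u, pairs$d))
        assign(k, c(if (exists(k, envir = idx)) get(k, envir = idx), i),
               envir = idx)
    }
  }
  lst <- as.list(idx)
  if (length(lst)) lst <- lst[order(names(lst))]
  new("RelationKnowledgebase", records = recs, pairIndex = lst)
}

#' Read a gene-to-KO assignment table
#'
#' Two-column tab-delimited text, gene id then KO id, no header; a gene may
#' appear on several rows and its KO assignments are aggregated. This is
#' the file shape emitted by automatic KO annotation servers.
#'
#' @param path file path.
#' @param sep field separator, tab by default.
#' @return a [GeneKOMap-class]
#' @export
readGeneKOMap <- function(path, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(GeneKOMap())
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L)
  if (length(bad))
    stop("row ", bad[1L], " has fewer than two fields: '", lines[bad[1L]],
         "'")
  gene <- vapply(parts, `[`, "", 1L)
  ko <- trimws(vapply(parts, `[`, "", 2L))
  GeneKOMap(split(ko, gene))
}

#' Gene-level edges permitted by the knowledgebase
#'
#' Transforms the KO-level pair index into gene-level ordered pairs for a
#' gene set of interest: \code{(g_u, g_d)} is returned exactly when some KO
#' of \code{g_u} and some KO of \code{g_d} form an indexed pair. Self-pairs
#' are excluded (Bayesian networks have no self-loops); distinct genes
#' sharing a KO with an indexed self-pair do yield cross-gene edges.
#'
#' @param kb a [RelationKnowledgebase-class].
#' @param komap a [GeneKOMap-class].
#' @param genes character vector of gene ids, all present in \code{komap}.
#' @return data.frame(from, to) of ordered gene pairs
#' @export
allowedGeneEdges <- function(kb, komap, genes) {
  genes <- unique(as.character(genes))
  missing_genes <- setdiff(genes, names(komap@map))
  if (length(missing_genes))
    stop("genes absent from the KO map: ",
         paste(missing_genes, collapse = ", "))
  if (!length(genes) || !length(kb@pairIndex)) return(.emptyEdges())
  # KO -> genes (restricted to the candidate set)
  ko2g <- new.env(parent = emptyenv())
  for (g in genes)
    for (k in komap@map[[g]])
      assign(k, c(if (exists(k, envir = ko2g)) get(k, envir = ko2g), g),
             envir = ko2g)
  pairs <- koPairs(kb)
  out_from <- character(0); out_to <- character(0)
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$from[i]; d <- pairs$to[i]
    if (!exists(u, envir = ko2g) || !exists(d, envir = ko2g)) next
    gu <- get(u, envir = ko2g); gd <- get(d, envir = ko2g)
    grid <- expand.grid(from = gu, to = gd, stringsAsFactors = FALSE)
    grid <- grid[grid$from != grid$to, , drop = FALSE]
    out_from <- c(out_from, grid$from)
    out_to <- c(out_to, grid$to)
  }
  out <- data.frame(from = out_from, to = out_to, stringsAsFactors = FALSE)
  out <- out[!duplicated(.edgeKey(out$from, out$to)), , drop = FALSE]
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a knowledgebase to tab-delimited text
#'
#' One row per record: upstream KOs (comma-joined), downstream KOs, record
#' type, compounds, source map.
#'
#' @param kb a [RelationKnowledgebase-class].
#' @param path output file.
#' @export
writeKnowledgebase <- function(kb, path) {
  r <- kb@records
  join <- function(l) vapply(l, paste, "", collapse = ",")
  out <- data.frame(upstream = join(r$upstream),
                    downstream = join(r$downstream),
                    type = r$record_type,
                    compounds = join(r$compounds),
                    source_map = r$source_map, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the ordered KO-pair index as an edge list
#'
#' @param kb a [RelationKnowledgebase-class].
#' @param path output file (TSV, columns \code{from}, \code{to}).
#' @export
writePairIndex <- function(kb, path) {
  write.table(koPairs(kb), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
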