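# Independent oracles and small fixture builders shared across tests.

# Graph-isomorphism oracle via igraph VF2 with vertex colors
# (element, charge, isotope, H count) and edge colors (bond order).
# Independent of the package's refinement-based canonicalization.
iso_oracle <- function(r1, r2) {
  if (nrow(r1$atoms) != nrow(r2$atoms) || nrow(r1$bonds) != nrow(r2$bonds))
    return(FALSE)
  vlab <- function(r) paste(r$atoms$elem, r$atoms$charge,
                            ifelse(is.na(r$atoms$isotope), 0L, r$atoms$isotope),
                            r$atoms$hcount)
  lv <- sort(unique(c(vlab(r1), vlab(r2))))
  g <- function(r) igraph::make_graph(t(as.matrix(r$bonds[, c("a1", "a2")])),
                                      n = nrow(r$atoms), directed = FALSE)
  igraph::isomorphic(g(r1), g(r2), method = "vf2",
                     vertex.color1 = match(vlab(r1), lv),
                     vertex.color2 = match(vlab(r2), lv),
                     edge.color1 = r1$bonds$order, edge.color2 = r2$bonds$order)
}

# Brute-force Venn partition: per-key membership scan.
venn_oracle <- function(sets) {
  keys <- unique(unlist(lapply(sets, `[[`, "keys")))
  masks <- vapply(keys, function(k)
    paste(vapply(sets, function(s) as.integer(k %in% s$keys), integer(1)),
          collapse = ""), character(1))
  table(masks)
}

# An SD file whose middle record has a corrupted counts line.
write_corrupt_sdf <- function(path) {
  recs <- lapply(c("good1", "good2", "good3"), function(id)
    example_mol("acetone", source_id = id))
  write_sdf(recs, path)
  lines <- readLines(path)
  counts <- which(grepl("V2000", lines))
  lines[counts[2]] <- " xx bad counts line V2000"
  writeLines(lines, path)
  path
}

expect_same_record <- function(a, b) {
  expect_identical(a$source_id, b$source_id)
  expect_equal(canonical_serialization(a), canonical_serialization(b))
}
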