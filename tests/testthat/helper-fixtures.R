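# Shared in-code fixtures. Everything is generated at test time; no files
# ship with the tests.

# A minimal SAM file written directly, for exercising the reader on
# hand-controlled records (CIGARs, NM tags, flags).
write_mini_sam <- function(path, records,
                           sq = c("taxA|m1" = 1000L, "taxA|m2" = 1000L,
                                  "taxB|m1" = 800L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, flag = 0L, rname = "taxA|m1", pos = 1L,
                       mapq = 42L, cigar = "100M", seq = strrep("A", 100L),
                       qual = strrep("I", 100L), nm = 0L,
                       with_nm = TRUE) {
  base <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  qname, flag, rname, pos, mapq, cigar, seq, qual)
  if (with_nm) paste0(base, sprintf("\tNM:i:%d", nm)) else base
}

# run the independent numpy MCL oracle; returns a list of clusters
mcl_oracle <- function(graph, inflation = 2) {
  script <- system.file("oracle", "mcl_reference.py", package = "eukscreen")
  stopifnot(nzchar(script))
  edges <- lapply(seq_len(nrow(graph$edges)), function(i)
    list(graph$edges$from[i], graph$edges$to[i], graph$edges$weight[i]))
  payload <- jsonlite::toJSON(list(nodes = graph$nodes, edges = edges,
                                   inflation = inflation),
                              auto_unbox = TRUE)
  out <- system2("python", script, input = as.character(payload),
                 stdout = TRUE)
  res <- jsonlite::fromJSON(paste(out, collapse = ""),
                            simplifyVector = FALSE)
  lapply(res, function(cl) sort(unlist(cl)))
}

# canonical form of a clustering for set-of-sets comparison
canonical_clusters <- function(cl) {
  cl <- lapply(cl, function(x) sort(unlist(x)))
  cl[order(vapply(cl, `[`, "", 1L))]
}
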