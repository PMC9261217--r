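# shared fixtures built in code

quiet_metrics <- function(...) suppressWarnings(compute_metrics(...))

# two linearly separable "sentiment" classes for model unit tests
toy_binary <- function(n_per_class = 10) {
  pos <- paste("service was", rep(c("good", "great", "fine"), length.out = n_per_class),
               "overall")
  neg <- paste("service was", rep(c("bad", "awful", "poor"), length.out = n_per_class),
               "overall")
  list(texts = c(pos, neg),
       labels = rep(c("pos", "neg"), each = n_per_class))
}

toy_multiclass <- function(n_per_class = 8) {
  words <- list(a = "alpha marker", b = "beta marker", c = "gamma marker")
  texts <- unlist(lapply(words, function(w) paste("sample shows", w, seq_len(n_per_class))))
  list(texts = unname(texts),
       labels = rep(names(words), each = n_per_class))
}

# normalised worked-example sentences with their reference classes
normalized_examples <- function(task) {
  ex <- example_sentences()
  ex <- ex[ex$task == task, ]
  ex$text <- normalize_text(ex$text)
  ex
}
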