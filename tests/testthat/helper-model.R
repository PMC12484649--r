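# Shared small-profile training run (40 synthetic patients, test profile
# L = 4): trained lazily on first use and reused by every test that needs a
# trained network. Seeds fixed so the run is reproducible.

trained_fixture <- function() {
  memo("trained_model", {
    n_pat <- 40
    recs <- lapply(cohort_params(n_pat, seed = 1000),
                   function(p) generate_record(p)$record)
    ids <- vapply(recs, function(r) r$patient_id, character(1))
    sp <- split_patients(ids, seed = 42)
    seg_of <- function(group) {
      out <- list()
      for (r in recs[ids %in% group]) {
        out <- c(out, filter_segments(segment_record(r))$accepted)
      }
      out
    }
    train <- seg_of(sp$train)
    val <- seg_of(sp$val)
    test <- seg_of(sp$test)
    model <- build_network(net_config(profile = "test"), seed = 7)
    model <- train_model(model, train, val,
                         train_config(max_epochs = 8, patience = 3,
                                      seed = 11))
    list(model = model, records = recs, ids = ids, split = sp,
         train = train, val = val, test = test)
  })
}

# pooled MAE of a prediction vector against a record's reference MAP
record_mae <- function(pred, record) {
  e <- pred - record$map_ref$value
  mean(abs(e[is.finite(e)]))
}
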