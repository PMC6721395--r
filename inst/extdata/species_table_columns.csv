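column,type,description
species,character,Species name; must match a tip label of the working tree exactly
family,character,Family name (used by the family-level jackknife)
learning_binary,character,"Binary learning state: stable or plastic (plastic = modifies syllable repertoire after the first breeding season)"
learning_ternary,character,"Ternary learning state: early, delayed, or plastic; empty when undetermined"
learning_years,numeric,"Continuous learning window in years on [0, 2]; 1.33 for delayed, 2 for plastic species"
syllable_repertoire,character,Semicolon-separated per-study mean counts of unique syllables per individual
song_repertoire,character,Semicolon-separated per-study mean counts of unique songs per individual
syllables_per_song,character,Semicolon-separated per-study mean counts of unique syllables per song
duration_s,character,Semicolon-separated per-study mean song durations in seconds
interval_s,character,Semicolon-separated per-study mean inter-song intervals in seconds (0 allowed for continuous singers)
polygynous_male_fraction,numeric,"Fraction of males with more than one social mate, in [0, 1]; empty when unknown"
epp_fraction,numeric,"Fraction of extra-pair young or nests, in [0, 1]; empty when unknown"
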