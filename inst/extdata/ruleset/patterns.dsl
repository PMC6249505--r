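# Packaged starter patterns, one per line:
#   <criterion>.<n>: LEX(name) | LEX?(name) | GAP(k) | LITERAL("word")
# A2c.1 encodes the published automaton for criterion A2c (frequency cue,
# up to 5 intervening word tokens, idiosyncratic-language term, optional
# speech term). The remaining patterns are reconstructed templates:
# impairment/trigger cue + bounded gap + criterion-specific behavior term.
A1a.1: LEX(Impaired) GAP(5) LEX(A1a_nonVerbalBehavior)
A1b.1: LEX(Impaired) GAP(5) LEX(A1b_peers)
A1c.1: LEX(Impaired) GAP(5) LEX(A1c_sharing)
A1d.1: LEX(Impaired) GAP(5) LEX(A1d_engage)
A2a.1: LEX(Impaired) GAP(5) LEX(A2a_speech)
A2b.1: LEX(A2b_transact) GAP(5) LEX(A2b_recepLang)
A2b.2: LEX(Impaired) GAP(5) LEX(A2b_recepLang)
A2c.1: LEX(A2c_frequent) GAP(5) LEX(A2c_idiosyncratic) LEX?(A2c_speech)
A2c.2: LEX(Impaired) GAP(5) LEX(A2c_idiosyncratic)
A2d.1: LEX(Impaired) GAP(5) LEX(A2d_play)
A3a.1: LEX(A3a_obsess) GAP(5) LEX(A3_object)
A3b.1: LEX(A3b_nonFunctionalPlay) GAP(5) LEX(A3_object)
A3b.2: LEX(Impaired) GAP(5) LEX(A3b_routine)
A3c.1: LEX(A3c_abnormal) GAP(5) LEX(Body_parts)
A3d.1: LEX(A3d_sensitive) GAP(5) LEX(A3d_stimuli)
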