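# Context cues: surface phrase = cue class (start | stop | negation).
started = start
start = start
starting = start
commenced = start
initiated = start
stopped = stop
stop = stop
stopping = stop
discontinued = stop
ceased = stop
withheld = stop
withdrawn = stop
no = negation
not = negation
denies = negation
no evidence of = negation
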