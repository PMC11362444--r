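maybe
perhaps
possibly
probably
might
may
seem
seems
seemed
appear*
guess
guesses
guessed
sort
sorta
kind
kinda
somewhat
somehow
sometimes
unsure
uncertain*
unclear
doubt*
suppose*
chance
chances
likely
unlikely
almost
nearly
apparently
hopefully
depend*
vague*
partly
mostly
roughly
approximate*
tend
tends
tended
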