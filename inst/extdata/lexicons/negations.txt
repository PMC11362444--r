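no
not
never
none
nothing
nobody
nowhere
neither
nor
cannot
can't
don't
won't
didn't
doesn't
isn't
aren't
wasn't
weren't
haven't
hasn't
hadn't
shouldn't
wouldn't
couldn't
mustn't
ain't
without
lack*
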