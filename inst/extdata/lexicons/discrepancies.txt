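should
would
could
ought
must
need
needs
needed
want
wants
wanted
wish
wishes
wished
hope
hopes
hoped
expect*
prefer*
rather
ideal*
regret*
mistak*
problem*
shouldn't
wouldn't
couldn't
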