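a
an
and
are
as
at
be
by
for
from
has
have
in
is
it
its
of
on
or
that
the
this
to
was
were
with
we
our
using
study
studies
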