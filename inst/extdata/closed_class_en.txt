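the
a
an
and
or
but
if
of
to
in
on
at
by
for
with
from
as
is
are
was
were
be
been
am
it
its
he
she
they
them
his
her
their
we
us
our
you
your
i
me
my
this
that
these
those
not
no
so
than
then
there
here
what
which
who
when
where
how
why
will
would
can
could
should
must
may
might
do
does
did
have
has
had
about
into
over
under
between
through
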